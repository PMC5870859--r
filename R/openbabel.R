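# Internal bridge to the Open Babel toolkit.  All structure handling --
# SMILES parsing, canonicalisation, charge neutralisation, molecular
# descriptors and ECFP_4 fingerprints -- is delegated to the `obabel`
# executable, driven in batch over temporary files.  Molecules are tracked
# through each call by an integer title so that per-record failures can be
# reported instead of silently dropped.

PERIODIC_TABLE <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58,
  Pr = 59, Nd = 60, Pm = 61, Sm = 62, Eu = 63, Gd = 64, Tb = 65, Dy = 66,
  Ho = 67, Er = 68, Tm = 69, Yb = 70, Lu = 71, Hf = 72, Ta = 73, W = 74,
  Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82,
  Bi = 83, Po = 84, At = 85, Rn = 86, Fr = 87, Ra = 88, Ac = 89, Th = 90,
  Pa = 91, U = 92, Np = 93, Pu = 94)

ob_assert_available <- function() {
  if (!nzchar(Sys.which("obabel")))
    stop("the 'obabel' executable (Open Babel >= 3) is required on PATH",
         call. = FALSE)
}

# Run obabel over a batch of SMILES.  Returns the raw output lines; inputs
# are titled 1..n so callers can align results with their inputs.  `extra`
# holds additional command-line arguments (e.g. "--neutralize").
ob_batch <- function(smiles, out_format, extra = character()) {
  ob_assert_available()
  fin <- tempfile(fileext = ".smi")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles), sep = "\t"), fin)
  out <- suppressWarnings(system2(
    "obabel", c(fin, paste0("-o", out_format), "-e", extra),
    stdout = TRUE, stderr = FALSE))
  out[nzchar(out)]
}

# Canonical SMILES for each input; NA where Open Babel could not parse.
# `neutralize` additionally applies the +1/-1 charge neutralisation op and
# drops explicit hydrogens, the normalisation used during curation.
ob_canonical <- function(smiles, neutralize = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  parseable <- !is.na(smiles) & nzchar(smiles)
  res <- rep(NA_character_, n)
  if (any(parseable)) {
    extra <- if (neutralize) c("-d", "--neutralize") else character()
    lines <- ob_batch(smiles[parseable], "can", extra)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    idx <- as.integer(vapply(parts[ok], `[`, "", 2L))
    res[which(parseable)[idx]] <- vapply(parts[ok], `[`, "", 1L)
  }
  res
}

# Molecular formula and weight per input SMILES (NA rows on parse failure).
ob_descriptors <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(formula = rep(NA_character_, n), mw = rep(NA_real_, n))
  parseable <- !is.na(smiles) & nzchar(smiles)
  if (!any(parseable)) return(out)
  lines <- ob_batch(smiles[parseable], "smi", c("--append", "formula MW"))
  parts <- strsplit(lines, "[\t ]+")
  ok <- lengths(parts) >= 4L
  idx <- as.integer(vapply(parts[ok], `[`, "", 2L))
  out$formula[which(parseable)[idx]] <- vapply(parts[ok], `[`, "", 3L)
  out$mw[which(parseable)[idx]] <- as.numeric(vapply(parts[ok], `[`, "", 4L))
  out
}

# Parse a Hill formula ("C9H8ClN O4" style tokens) into a named count
# vector keyed by element symbol.
parse_formula <- function(formula) {
  if (is.na(formula)) return(integer(0))
  # strip charge suffixes such as "+"/"-" that Open Babel appends to ions
  formula <- gsub("[+-]+$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  sym <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Z][a-z]?", "", toks)))
  cnt[is.na(cnt)] <- 1L
  tapply(cnt, sym, sum)
}

formula_elements <- function(formula) {
  counts <- parse_formula(formula)
  z <- PERIODIC_TABLE[names(counts)]
  sort(unname(z[!is.na(z)]))
}

formula_heavy_atoms <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts[names(counts) != "H"])
}
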