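#' ECFP_4 Morgan fingerprints
#'
#' Computes binary extended-connectivity fingerprints of radius 2 bonds
#' (ECFP_4) with Open Babel and folds them to a fixed width (default
#' 2048 bits) by OR-ing hash buckets.  Folding collisions between distinct
#' substructures are inherent to fixed-width fingerprints and accepted;
#' the computation is fully deterministic.
#'
#' @param smiles character vector of standardized SMILES.
#' @param ids compound identifiers used as row names (default the SMILES).
#' @param nbits folded width; must divide the native 4096-bit table.
#' @return integer 0/1 matrix, one row per compound, `nbits` columns.
#' @export
fingerprint <- function(smiles, ids = smiles, nbits = 2048L) {
  stopifnot(length(smiles) == length(ids), 4096L %% nbits == 0L)
  n <- length(smiles)
  if (n == 0L)
    return(matrix(integer(0), 0, nbits))
  lines <- ob_batch(smiles, "fps", c("-xf", "ECFP4"))
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  hex <- vapply(parts, `[`, "", 1L)
  idx <- as.integer(vapply(parts, `[`, "", 2L))
  if (length(idx) < n) {
    bad <- setdiff(seq_len(n), idx)
    stop("cannot fingerprint unparseable SMILES: ",
         paste(utils::head(smiles[bad], 5), collapse = ", "), call. = FALSE)
  }
  bits <- hex_to_bits(hex)               # n x 4096, FPS input order
  bits <- bits[order(idx), , drop = FALSE]
  folds <- 4096L %/% nbits
  out <- bits[, seq_len(nbits), drop = FALSE]
  for (k in seq_len(folds - 1L))
    out <- out | bits[, k * nbits + seq_len(nbits), drop = FALSE]
  out <- matrix(as.integer(out), n, nbits)
  rownames(out) <- ids
  out
}

# Expand FPS hex strings (MSB-first per nibble) into a 0/1 matrix.
hex_to_bits <- function(hex) {
  digits <- c(0:9, letters[1:6], LETTERS[1:6])
  values <- c(0:15, 10:15)
  nib <- t(vapply(0:15, function(v)
    as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L), integer(4)))
  t(vapply(strsplit(tolower(hex), ""), function(ch) {
    v <- values[match(ch, digits)]
    as.vector(t(nib[v + 1L, , drop = FALSE]))
  }, integer(nchar(hex[1]) * 4L)))
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` on the bit sets.  Two all-zero fingerprints are
#' defined as identical (similarity 1) with a warning; this only arises
#' for degenerate chemistry that the structure filter would have removed.
#'
#' @param a,b equal-width binary vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprint widths differ (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) {
    warning("Tanimoto of two empty fingerprints defined as 1")
    return(1)
  }
  inter / uni
}

#' Pairwise Tanimoto matrix between two fingerprint collections
#'
#' @param a,b binary matrices with equal column counts (rows = compounds).
#' @return numeric matrix of dimensions `nrow(a)` x `nrow(b)`.
#' @export
tanimoto_matrix <- function(a, b = a) {
  if (ncol(a) != ncol(b))
    stop("fingerprint widths differ (", ncol(a), " vs ", ncol(b), ")",
         call. = FALSE)
  am <- matrix(as.numeric(a), nrow(a), ncol(a))
  bm <- matrix(as.numeric(b), nrow(b), ncol(b))
  inter <- tcrossprod(am, bm)
  uni <- outer(rowSums(am), rowSums(bm), "+") - inter
  tc <- ifelse(uni == 0, 1, inter / uni)
  dimnames(tc) <- list(rownames(a), rownames(b))
  tc
}

#' Nearest-neighbour similarity of a query set against a reference set
#'
#' For every query compound the maximum Tanimoto similarity to any
#' reference compound is computed; self-pairs (shared compound id) are
#' excluded so a set can be screened against a superset of itself.  Used
#' for the human-versus-orthologue chemical-space comparison.
#'
#' @param query_fps,reference_fps binary fingerprint matrices with
#'   compound ids as row names.
#' @param groups optional per-query grouping labels (e.g. target class or
#'   species) carried into the summary.
#' @return an `nn_summary`: data.frame of `compound_id`, `nn_tc`, `group`.
#' @export
nn_to_reference <- function(query_fps, reference_fps, groups = NULL) {
  if (nrow(reference_fps) == 0L)
    stop("reference set is empty; nearest-neighbour similarity undefined",
         call. = FALSE)
  tc <- tanimoto_matrix(query_fps, reference_fps)
  qid <- rownames(query_fps); rid <- rownames(reference_fps)
  if (!is.null(qid) && !is.null(rid))
    tc[outer(qid, rid, "==")] <- NA_real_
  nn <- apply(tc, 1L, max, na.rm = TRUE)
  nn[!is.finite(nn)] <- NA_real_
  out <- data.frame(compound_id = if (is.null(qid))
    as.character(seq_len(nrow(query_fps))) else qid,
    nn_tc = unname(nn),
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    stringsAsFactors = FALSE)
  class(out) <- c("nn_summary", "data.frame")
  out
}

#' Nearest-neighbour similarity within one group of compounds
#'
#' Leave-one-out maximum Tanimoto similarity inside a single set, the
#' intra-group diversity measure for orthologue compound groups.
#'
#' @param fps binary fingerprint matrix with at least two rows.
#' @inheritParams nn_to_reference
#' @return an `nn_summary` data.frame.
#' @export
intra_group_nn <- function(fps, groups = NULL) {
  if (nrow(fps) < 2L)
    stop("intra-group similarity undefined for fewer than 2 compounds",
         call. = FALSE)
  tc <- tanimoto_matrix(fps, fps)
  diag(tc) <- NA_real_
  nn <- apply(tc, 1L, max, na.rm = TRUE)
  out <- data.frame(compound_id = if (is.null(rownames(fps)))
    as.character(seq_len(nrow(fps))) else rownames(fps),
    nn_tc = unname(nn),
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    stringsAsFactors = FALSE)
  class(out) <- c("nn_summary", "data.frame")
  out
}

#' @export
summary.nn_summary <- function(object, cutoffs = c(0.4), ...) {
  grp <- if (all(is.na(object$group))) rep("all", nrow(object))
         else object$group
  per <- do.call(rbind, lapply(split(object$nn_tc, grp), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(n = length(v), q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  per$group <- rownames(per)
  rownames(per) <- NULL
  fr <- vapply(cutoffs, function(ct) fraction_below(object, ct), 0)
  list(per_group = per[, c("group", "n", "q25", "median", "q75")],
       fraction_below = stats::setNames(fr, paste0("tc<", cutoffs)))
}

#' Fraction of compounds whose nearest neighbour falls below a similarity
#' cut-off
#'
#' @param nn an `nn_summary`.
#' @param cutoff Tanimoto threshold.
#' @return proportion in `[0, 1]`.
#' @export
fraction_below <- function(nn, cutoff) {
  v <- nn$nn_tc[!is.na(nn$nn_tc)]
  if (!length(v)) return(NA_real_)
  mean(v < cutoff)
}

#' Cache fingerprints to a plain-text file
#'
#' One line per compound: `id<TAB><hex>`, restoring to the same matrix
#' with [read_fingerprints()].
#'
#' @param fps binary fingerprint matrix with ids as row names.
#' @param path output file.
#' @export
write_fingerprints <- function(fps, path) {
  hx <- apply(fps, 1L, function(b) {
    nib <- colSums(matrix(b, 4L) * c(8L, 4L, 2L, 1L))
    paste(c(0:9, letters[1:6])[nib + 1L], collapse = "")
  })
  writeLines(paste(rownames(fps), hx, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  hex <- vapply(parts, `[`, "", 2L)
  out <- hex_to_bits(hex)
  out <- matrix(as.integer(out), nrow(out), ncol(out))
  rownames(out) <- vapply(parts, `[`, "", 1L)
  out
}
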