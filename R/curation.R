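#' Curation settings for bioactivity extraction
#'
#' Collects the thresholds used when turning raw ChEMBL/PubChem-style
#' bioactivity tables into labelled training records:
#' \describe{
#'   \item{pchembl_active_min}{minimum pChEMBL for an active annotation;
#'     the default 5.0 corresponds to 10 uM.}
#'   \item{confidence_min_exclusive}{assay confidence scores must exceed
#'     this value (strictly), so protein complexes are retained while
#'     poorly-mapped assays are not.}
#'   \item{mw_min, mw_max}{allowed molecular-weight window in Daltons.}
#'   \item{forbidden_z_ranges}{list of inclusive atomic-number intervals
#'     whose presence disqualifies a compound.  The defaults exclude
#'     transition and heavy elements (Z 21-32, 36-52 and Z >= 54) while
#'     keeping iodine (Z = 53), consistent with drug-like chemistry.}
#'   \item{require_carbon}{drop structures without carbon.}
#'   \item{min_actives}{minimum number of active training compounds a
#'     target must reach to be modelled.}
#' }
#'
#' @param pchembl_active_min,confidence_min_exclusive,mw_min,mw_max,require_carbon,min_actives
#'   see Description.
#' @param forbidden_z_ranges list of `c(lo, hi)` inclusive intervals; `Inf`
#'   is allowed as an upper bound.
#' @return an object of class `curation_config`.
#' @export
curation_config <- function(pchembl_active_min = 5,
                            confidence_min_exclusive = 5,
                            mw_min = 100, mw_max = 1000,
                            forbidden_z_ranges = list(c(21, 32), c(36, 52),
                                                      c(54, Inf)),
                            require_carbon = TRUE,
                            min_actives = 10) {
  stopifnot(pchembl_active_min > 0, mw_min < mw_max, min_actives >= 1)
  rng <- do.call(rbind, lapply(forbidden_z_ranges, function(r) {
    stopifnot(length(r) == 2, r[1] <= r[2])
    r
  }))
  if (!is.null(rng) && nrow(rng) > 1) {
    o <- order(rng[, 1])
    rng <- rng[o, , drop = FALSE]
    if (any(rng[-1, 1] <= rng[-nrow(rng), 2]))
      stop("forbidden_z_ranges must be non-overlapping", call. = FALSE)
    forbidden_z_ranges <- lapply(seq_len(nrow(rng)), function(i) rng[i, ])
  }
  structure(list(pchembl_active_min = pchembl_active_min,
                 confidence_min_exclusive = confidence_min_exclusive,
                 mw_min = mw_min, mw_max = mw_max,
                 forbidden_z_ranges = forbidden_z_ranges,
                 require_carbon = require_carbon,
                 min_actives = min_actives),
            class = "curation_config")
}

#' @export
print.curation_config <- function(x, ...) {
  cat("Bioactivity curation settings\n")
  cat(sprintf("  active if pChEMBL >= %.2f (or comment 'active')\n",
              x$pchembl_active_min))
  cat(sprintf("  assay confidence   > %d\n", x$confidence_min_exclusive))
  cat(sprintf("  molecular weight   [%g, %g] Da\n", x$mw_min, x$mw_max))
  rng <- vapply(x$forbidden_z_ranges, function(r)
    sprintf("%g-%g", r[1], r[2]), "")
  cat("  forbidden Z ranges ", paste(rng, collapse = ", "), "\n", sep = "")
  cat(sprintf("  min actives/target %d\n", x$min_actives))
  invisible(x)
}

#' Standardize SMILES structures
#'
#' Applies the curation-time normalisation to raw SMILES: the largest
#' fragment is kept (counter-ions and solvents dropped; ties broken by
#' heavy-atom count, then lexicographic canonical-SMILES order), +1/-1
#' charges are neutralised where valence allows, explicit hydrogens are
#' removed and the result is emitted as an Open Babel canonical SMILES.
#' The operation is idempotent.  Unparseable inputs are reported in the
#' result rather than silently dropped.
#'
#' @param smiles character vector of raw SMILES.
#' @return data.frame with columns `input`, `smiles` (standardized, `NA`
#'   on failure), `ok` (logical) and `reason` (`NA` or the failure cause).
#' @export
standardize_structures <- function(smiles) {
  n <- length(smiles)
  res <- data.frame(input = as.character(smiles),
                    smiles = rep(NA_character_, n),
                    ok = rep(FALSE, n),
                    reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  blank <- is.na(smiles) | !nzchar(trimws(smiles))
  res$reason[blank] <- "empty SMILES"
  todo <- which(!blank)
  if (!length(todo)) return(res)

  # explode multi-fragment inputs; '.' is the SMILES component separator
  frags <- strsplit(smiles[todo], ".", fixed = TRUE)
  owner <- rep(todo, lengths(frags))
  frag <- unlist(frags, use.names = FALSE)
  can <- ob_canonical(frag)
  bad_owner <- unique(owner[is.na(can)])
  res$reason[bad_owner] <- "unparseable SMILES"
  keep <- !(owner %in% bad_owner)
  if (any(keep)) {
    owner <- owner[keep]; can <- can[keep]
    heavy <- vapply(ob_descriptors(can)$formula, formula_heavy_atoms, 0)
    # largest fragment per input, ties by canonical string order
    o <- order(owner, -heavy, can, method = "radix")
    first <- !duplicated(owner[o])
    win_owner <- owner[o][first]
    winners <- can[o][first]
    std <- ob_canonical(winners, neutralize = TRUE)
    res$smiles[win_owner] <- std
    res$ok[win_owner] <- !is.na(std)
    res$reason[win_owner[is.na(std)]] <- "standardization failed"
  }
  res
}

#' Compute the structural properties used by the curation filter
#'
#' @param smiles character vector of (standardized) SMILES.
#' @return data.frame with `smiles`, `formula`, `mw` (Daltons), `n_heavy`
#'   and a list-column `elements` of atomic numbers present.
#' @export
compound_properties <- function(smiles) {
  d <- ob_descriptors(smiles)
  data.frame(smiles = as.character(smiles),
             formula = d$formula,
             mw = d$mw,
             n_heavy = vapply(d$formula, formula_heavy_atoms, 0),
             elements = I(lapply(d$formula, formula_elements)),
             stringsAsFactors = FALSE)
}

#' Element and molecular-weight structure filter
#'
#' A compound fails when it contains no carbon, contains any atom whose
#' atomic number falls inside a forbidden interval, or its molecular
#' weight lies outside the configured window.  The reported reason is the
#' first rule failed, checked in that order.
#'
#' @param properties data.frame from [compound_properties()].
#' @param config a [curation_config()].
#' @return data.frame with logical `pass` and character `reason`.
#' @export
structure_filter <- function(properties, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  n <- nrow(properties)
  pass <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    z <- properties$elements[[i]]
    if (is.na(properties$mw[i]) || length(z) == 0L) {
      pass[i] <- FALSE; reason[i] <- "unparseable structure"; next
    }
    if (config$require_carbon && !(6L %in% z)) {
      pass[i] <- FALSE; reason[i] <- "no carbon"; next
    }
    forb <- vapply(config$forbidden_z_ranges, function(r)
      any(z >= r[1] & z <= r[2]), TRUE)
    if (any(forb)) {
      r <- config$forbidden_z_ranges[[which(forb)[1]]]
      pass[i] <- FALSE
      reason[i] <- sprintf("forbidden element (Z in [%g, %g])", r[1], r[2])
      next
    }
    if (properties$mw[i] < config$mw_min || properties$mw[i] > config$mw_max) {
      pass[i] <- FALSE
      reason[i] <- sprintf("molecular weight %.1f outside [%g, %g]",
                           properties$mw[i], config$mw_min, config$mw_max)
    }
  }
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Read / write bioactivity tables
#'
#' Tables are delimited text (TSV by default, CSV for `.csv` paths) with
#' named header columns: `compound_id`, `smiles`, `target_accession`,
#' `species`, `standard_value`, `standard_units`, `standard_type`,
#' `assay_type`, `confidence`, `activity_comment`, `date`, `source`.
#' On read, a `pchembl` column is derived from `standard_value` /
#' `standard_units` for affinity endpoints with molar-convertible units;
#' other records keep `pchembl = NA` and can only enter the active set via
#' their activity comment.
#'
#' @param path file path.
#' @return data.frame of bioactivity records.
#' @export
read_bioactivity <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""))
  needed <- c("compound_id", "smiles", "target_accession", "species",
              "standard_value", "standard_units", "standard_type",
              "assay_type", "confidence", "activity_comment", "date",
              "source")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("bioactivity table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$date <- as.Date(df$date)
  affinity <- df$standard_type %in% c("Ki", "Kd", "IC50", "EC50") &
    !is.na(df$standard_value) & df$standard_value > 0 &
    !is.na(df$standard_units) & convertible_units(df$standard_units)
  df$pchembl <- NA_real_
  if (any(affinity))
    df$pchembl[affinity] <- to_pchembl(df$standard_value[affinity],
                                       df$standard_units[affinity])
  df
}

#' @rdname read_bioactivity
#' @param records data.frame of bioactivity records.
#' @export
write_bioactivity <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Select active bioactivity records
#'
#' Keeps records from binding or functional assays with assay confidence
#' strictly above the configured cut-off that are active either by
#' affinity (pChEMBL at or above `pchembl_active_min`) or by an activity
#' comment declaring them active (the route percentage activation /
#' inhibition endpoints take, which carry no pChEMBL).  Duplicate
#' measurements of one structure at one target in one species collapse to
#' a single record keeping the earliest date, so a later time-series split
#' sees each structure at its first appearance.
#'
#' @param records bioactivity data.frame (see [read_bioactivity()]); a
#'   standardized `smiles` column is assumed.
#' @param config a [curation_config()].
#' @return list with `records` (the labelled actives) and `rejected`
#'   (dropped rows with a reason column).
#' @export
select_actives <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  reason <- rep(NA_character_, nrow(records))
  no_target <- is.na(records$target_accession) |
    !nzchar(records$target_accession)
  reason[no_target] <- "missing target accession"
  assay_ok <- records$assay_type %in% c("binding", "functional", "B", "F")
  reason[is.na(reason) & !assay_ok] <- "assay type not binding/functional"
  conf_ok <- !is.na(records$confidence) &
    records$confidence > config$confidence_min_exclusive
  reason[is.na(reason) & !conf_ok] <- "insufficient assay confidence"
  comment_active <- !is.na(records$activity_comment) &
    tolower(trimws(records$activity_comment)) == "active"
  affinity_active <- !is.na(records$pchembl) &
    records$pchembl >= config$pchembl_active_min
  reason[is.na(reason) & !(comment_active | affinity_active)] <-
    "below activity threshold"
  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]

  # collapse duplicates on (structure, target, species): earliest date wins,
  # ties broken by original row order so the result is order-invariant
  if (nrow(kept)) {
    key <- paste(kept$smiles, kept$target_accession, kept$species,
                 sep = "\r")
    o <- order(key, kept$date, na.last = TRUE, method = "radix")
    kept <- kept[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
    kept <- kept[order(match(rownames(kept), rownames(records))), ,
                 drop = FALSE]
    kept$label <- "active"
  }
  rownames(kept) <- rownames(rejected) <- NULL
  list(records = kept, rejected = rejected)
}

#' Resolve active/inactive label conflicts between two curated sources
#'
#' When the same (standardized structure, target) pair is annotated active
#' in the manually curated ChEMBL-like source and inactive in the
#' screening-derived PubChem-like source, the active annotation wins and
#' the inactive rows are discarded.  The number of discarded pairs is
#' reported.
#'
#' @param actives curated active records.
#' @param inactives curated inactive records.
#' @return list with `actives` (unchanged), `inactives` (pruned) and
#'   `n_conflicts` (distinct conflicting pairs removed).
#' @export
resolve_conflicting_labels <- function(actives, inactives) {
  akey <- unique(paste(actives$smiles, actives$target_accession, sep = "\r"))
  ikey <- paste(inactives$smiles, inactives$target_accession, sep = "\r")
  clash <- ikey %in% akey
  list(actives = actives,
       inactives = inactives[!clash, , drop = FALSE],
       n_conflicts = length(unique(ikey[clash])))
}
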