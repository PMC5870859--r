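#' Read a HomoloGene-style orthologue table
#'
#' Expects delimited text with columns `group_id`, `taxon_id`,
#' `accession`, `gene_symbol`, `prot_change` (ratio of amino-acid
#' differences between the group member and its human counterpart, in
#' `[0, 1]`, possibly missing).  The table is turned into one row per
#' human-orthologue pair within each homology group.
#'
#' @param path file path (TSV; CSV for `.csv`).
#' @param human_taxon taxon label identifying the human rows.
#' @return data.frame of mappings: `group_id`, `human_accession`,
#'   `orthologue_accession`, `orthologue_species`, `prot_change`.
#' @export
read_homologene <- function(path, human_taxon = "9606") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""))
  homologene_mappings(df, human_taxon)
}

#' @rdname read_homologene
#' @param df an in-memory HomoloGene-style table with the same columns.
#' @export
homologene_mappings <- function(df, human_taxon = "9606") {
  df$taxon_id <- as.character(df$taxon_id)
  needed <- c("group_id", "taxon_id", "accession", "prot_change")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("orthologue table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(split(df, df$group_id), function(g) {
    hum <- g[g$taxon_id == human_taxon, , drop = FALSE]
    oth <- g[g$taxon_id != human_taxon, , drop = FALSE]
    if (!nrow(hum) || !nrow(oth)) return(NULL)
    data.frame(group_id = oth$group_id,
               human_accession = hum$accession[1],
               orthologue_accession = oth$accession,
               orthologue_species = as.character(oth$taxon_id),
               prot_change = oth$prot_change,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  bad <- !is.na(out$prot_change) &
    (out$prot_change < 0 | out$prot_change > 1)
  if (any(bad))
    stop("prot_change outside [0, 1] for group(s): ",
         paste(unique(out$group_id[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Merge orthologue actives into human target training sets
#'
#' Active records measured at orthologue targets are re-assigned to the
#' mapped human accession and appended to the human actives, with removal
#' of duplicate SMILES: when the same standardized structure is already
#' active at the human target, the human-provenance copy is kept.
#' Orthologue records whose accession has no mapping are skipped and
#' logged, not fatal.
#'
#' @param human_actives data.frame of curated human actives
#'   (`target_accession`, `compound_id`, `smiles`, plus any other columns).
#' @param orthologue_actives curated actives at orthologue accessions.
#' @param mappings mapping table from [read_homologene()].
#' @return list with `actives` (merged long table carrying a `provenance`
#'   column), `log` (per-target counts added/duplicate) and `orphans`
#'   (unmappable orthologue accessions with record counts).
#' @export
merge_orthologue_actives <- function(human_actives, orthologue_actives,
                                     mappings) {
  human_actives$provenance <- "human"
  if (is.null(orthologue_actives) || nrow(orthologue_actives) == 0L) {
    return(list(actives = human_actives,
                log = data.frame(target_accession = character(0),
                                 n_added = integer(0),
                                 n_duplicate = integer(0)),
                orphans = data.frame(accession = character(0),
                                     n_records = integer(0))))
  }
  hit <- match(orthologue_actives$target_accession,
               mappings$orthologue_accession)
  orphan <- is.na(hit)
  orphan_tab <- table(orthologue_actives$target_accession[orphan])
  orphans <- data.frame(accession = names(orphan_tab),
                        n_records = as.integer(orphan_tab),
                        stringsAsFactors = FALSE)

  ortho <- orthologue_actives[!orphan, , drop = FALSE]
  ortho$provenance <- if (nrow(ortho))
    paste0("orthologue:", ortho$species) else character(0)
  ortho$target_accession <- mappings$human_accession[hit[!orphan]]

  merged <- rbind(human_actives[, names(ortho), drop = FALSE], ortho)
  key <- paste(merged$target_accession, merged$smiles, sep = "\r")
  dup <- duplicated(key)          # human rows come first, so they win
  kept <- merged[!dup, , drop = FALSE]
  rownames(kept) <- NULL

  added <- kept[kept$provenance != "human", , drop = FALSE]
  dup_ortho <- merged[dup & merged$provenance != "human", , drop = FALSE]
  tgts <- sort(unique(c(added$target_accession,
                        dup_ortho$target_accession)))
  add_tab <- table(factor(added$target_accession, levels = tgts))
  dup_tab <- table(factor(dup_ortho$target_accession, levels = tgts))
  log <- data.frame(target_accession = tgts,
                    n_added = as.integer(add_tab),
                    n_duplicate = as.integer(dup_tab),
                    stringsAsFactors = FALSE)
  list(actives = kept, log = log, orphans = orphans)
}

#' Apply the minimum-actives threshold to merged training sets
#'
#' Targets whose merged active count falls below `min_actives` are
#' dropped.  Targets that pass the threshold only thanks to orthologue
#' additions -- models that could not exist from human data alone -- are
#' reported as `newly_enabled`.
#'
#' @param actives merged long table from [merge_orthologue_actives()].
#' @param min_actives required number of active training compounds.
#' @return list with `actives` (retained rows), `kept_targets`,
#'   `newly_enabled` and `dropped_targets`.
#' @export
apply_min_actives <- function(actives, min_actives = 10) {
  total <- table(actives$target_accession)
  human <- table(actives$target_accession[actives$provenance == "human"])
  kept <- names(total)[total >= min_actives]
  human_n <- as.integer(human[kept])
  human_n[is.na(human_n)] <- 0L
  newly <- kept[human_n < min_actives]
  list(actives = actives[actives$target_accession %in% kept, , drop = FALSE],
       kept_targets = kept,
       newly_enabled = newly,
       dropped_targets = setdiff(names(total), kept))
}

#' Per-class model counts before and after orthologue inclusion
#'
#' @param targets_before,targets_after character vectors of modelled
#'   target accessions in each arm.
#' @param target_classes data.frame with `target_accession` and `class`;
#'   targets with no (or unknown) annotation are bucketed as `"other"`.
#' @param augmented_targets optional vector of targets that received
#'   orthologue compounds, reported as an overall share of the after-arm.
#' @return list with `per_class` (counts and percentage change) and
#'   `share_augmented` (proportion or `NA`).
#' @export
coverage_summary <- function(targets_before, targets_after, target_classes,
                             augmented_targets = NULL) {
  cls <- function(t) {
    k <- target_classes$class[match(t, target_classes$target_accession)]
    k[is.na(k)] <- "other"
    k
  }
  lev <- sort(unique(c(cls(targets_before), cls(targets_after))))
  before <- table(factor(cls(targets_before), levels = lev))
  after <- table(factor(cls(targets_after), levels = lev))
  per <- data.frame(class = lev,
                    n_before = as.integer(before),
                    n_after = as.integer(after))
  per$pct_change <- ifelse(per$n_before == 0, NA_real_,
                           100 * (per$n_after - per$n_before) / per$n_before)
  share <- if (is.null(augmented_targets)) NA_real_
           else mean(targets_after %in% augmented_targets)
  list(per_class = per, share_augmented = share)
}

#' Active/inactive conflict analysis across orthologue mappings
#'
#' For each human-orthologue target mapping, every mapped record at the
#' source accession is checked against the partner records at the other
#' accession: a mapped record conflicts when the identical standardized
#' SMILES carries the opposite annotation at the mapping partner.  Both
#' published directions are expressed through the argument roles: mapping
#' orthologue *actives* against human *inactives* (`records` = actives,
#' `partner_records` = inactives, `mapped_side = "orthologue"`), and
#' mapping orthologue screening *inactives* against human *actives*
#' (`records` = inactives, `partner_records` = actives).  Counting is
#' mapping-level: a compound measured at an accession involved in several
#' mappings is counted once per mapping row.
#'
#' @param records the records being mapped (each row one measurement with
#'   `smiles` and `target_accession`).
#' @param partner_records the opposite-annotation records checked for the
#'   same structures at the partner accession.
#' @param mappings mapping table from [read_homologene()].
#' @param mapped_side which accession of each mapping the mapped
#'   `records` live at.
#' @param direction free-text label stored in the report.
#' @return a `conflict_report`: per-mapping rows (`n_mapped`,
#'   `n_conflicting`) and totals including the compatibility percentage
#'   `100 * (1 - N_conflicting / N_mapped)` and the fraction of mappings
#'   free of conflicts.
#' @export
conflict_analysis <- function(records, partner_records, mappings,
                              mapped_side = c("orthologue", "human"),
                              direction = NULL) {
  mapped_side <- match.arg(mapped_side)
  if (is.null(direction))
    direction <- paste0("mapped side: ", mapped_side)
  if (is.null(mappings) || nrow(mappings) == 0L) {
    per <- data.frame(human_accession = character(0),
                      orthologue_accession = character(0),
                      n_mapped = integer(0), n_conflicting = integer(0))
    return(new_conflict_report(per, direction))
  }
  if (mapped_side == "orthologue") {
    mapped_acc <- mappings$orthologue_accession
    partner_acc <- mappings$human_accession
  } else {
    mapped_acc <- mappings$human_accession
    partner_acc <- mappings$orthologue_accession
  }
  act_split <- split(records$smiles, records$target_accession)
  ina_split <- split(partner_records$smiles,
                     partner_records$target_accession)
  n_mapped <- integer(nrow(mappings))
  n_conf <- integer(nrow(mappings))
  for (i in seq_len(nrow(mappings))) {
    a <- act_split[[mapped_acc[i]]]
    n_mapped[i] <- length(a)
    if (length(a))
      n_conf[i] <- sum(a %in% ina_split[[partner_acc[i]]])
  }
  per <- data.frame(human_accession = mappings$human_accession,
                    orthologue_accession = mappings$orthologue_accession,
                    n_mapped = n_mapped, n_conflicting = n_conf,
                    stringsAsFactors = FALSE)
  new_conflict_report(per, direction)
}

new_conflict_report <- function(per_mapping, direction) {
  with_data <- per_mapping[per_mapping$n_mapped > 0, , drop = FALSE]
  n_mapped <- sum(per_mapping$n_mapped)
  n_conf <- sum(per_mapping$n_conflicting)
  structure(list(
    per_mapping = per_mapping[order(-per_mapping$n_conflicting), ,
                              drop = FALSE],
    direction = direction,
    totals = list(
      n_mapped = n_mapped,
      n_conflicting = n_conf,
      n_pairs = nrow(with_data),
      n_pairs_conflict_free = sum(with_data$n_conflicting == 0),
      conflict_pct = if (n_mapped > 0) 100 * n_conf / n_mapped else NA_real_,
      compatibility_pct = if (n_mapped > 0)
        100 * (1 - n_conf / n_mapped) else NA_real_,
      pair_conflict_free_frac = if (nrow(with_data) > 0)
        mean(with_data$n_conflicting == 0) else NA_real_)),
    class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  t <- x$totals
  cat("Orthologue bioactivity conflict report (", x$direction, ")\n",
      sep = "")
  cat(sprintf("  mapped bioactivities : %d\n", t$n_mapped))
  cat(sprintf("  conflicting          : %d (%.2f%%)\n",
              t$n_conflicting, t$conflict_pct))
  cat(sprintf("  compatibility        : %.2f%%\n", t$compatibility_pct))
  cat(sprintf("  target pairs         : %d (%d conflict-free, %.1f%%)\n",
              t$n_pairs, t$n_pairs_conflict_free,
              100 * t$pair_conflict_free_frac))
  invisible(x)
}

#' Concordance of paired human / orthologue affinity measurements
#'
#' For compounds measured at both partners of a mapping, reports the
#' squared Pearson correlation of the pChEMBL values (overall and per
#' `standard_units` x `standard_type` x `assay_type` group), the median
#' absolute pChEMBL discordance, and the fraction of pairs active in both
#' species at the given cut-off.  Groups with fewer than 3 pairs report an
#' undefined (NA) correlation rather than zero.
#'
#' @param pairs data.frame with `pchembl_human`, `pchembl_orthologue` and
#'   optionally `standard_units`, `standard_type`, `assay_type`.
#' @param activity_cutoff pChEMBL threshold for calling both-active.
#' @return a `concordance_report`.
#' @export
concordance_analysis <- function(pairs, activity_cutoff = 5) {
  h <- pairs$pchembl_human
  o <- pairs$pchembl_orthologue
  ok <- !is.na(h) & !is.na(o)
  h <- h[ok]; o <- o[ok]
  r2 <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)^2
  }
  grp_cols <- intersect(c("standard_units", "standard_type", "assay_type"),
                        names(pairs))
  per_group <- NULL
  if (length(grp_cols)) {
    key <- do.call(paste, c(pairs[ok, grp_cols, drop = FALSE], sep = " / "))
    per_group <- do.call(rbind, lapply(split(seq_along(h), key), function(i)
      data.frame(n = length(i), r_squared = r2(h[i], o[i]),
                 median_abs_discordance = stats::median(abs(h[i] - o[i])))))
    per_group$group <- rownames(per_group)
    rownames(per_group) <- NULL
    per_group <- per_group[, c("group", "n", "r_squared",
                               "median_abs_discordance")]
  }
  structure(list(
    n_pairs = length(h),
    r_squared = r2(h, o),
    per_group = per_group,
    median_abs_discordance = if (length(h)) stats::median(abs(h - o))
                             else NA_real_,
    activity_cutoff = activity_cutoff,
    n_both_active = sum(h >= activity_cutoff & o >= activity_cutoff),
    frac_both_active = if (length(h))
      mean(h >= activity_cutoff & o >= activity_cutoff) else NA_real_),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Human / orthologue affinity concordance\n")
  cat(sprintf("  pairs                  : %d\n", x$n_pairs))
  cat(sprintf("  overall R-squared      : %.3f\n", x$r_squared))
  cat(sprintf("  median |delta pChEMBL| : %.2f\n",
              x$median_abs_discordance))
  cat(sprintf("  both active (>= %.1f)  : %d (%.0f%%)\n",
              x$activity_cutoff, x$n_both_active,
              100 * x$frac_both_active))
  invisible(x)
}

#' Discordance binned by the protein-change ratio of the mapping
#'
#' Assigns each measurement pair to a bin of the HomoloGene-style
#' protein-change ratio (`[0, w)`, `[w, 2w)`, ...) and reports the median
#' absolute pChEMBL discordance per bin, together with the squared Pearson
#' correlation between the ratio and the discordance (the trend
#' statistic).  Pairs whose mapping lacks a protein-change value are
#' excluded and counted.
#'
#' @param pairs data.frame with `pchembl_human`, `pchembl_orthologue` and
#'   either a `prot_change` column or `human_accession` /
#'   `orthologue_accession` columns resolvable through `mappings`.
#' @param mappings optional mapping table used to look up `prot_change`.
#' @param bin_width ratio bin width (default 0.1).
#' @return list with `per_bin`, `trend_r_squared`, `n_excluded_missing`.
#' @export
prot_change_binning <- function(pairs, mappings = NULL, bin_width = 0.1) {
  pc <- pairs$prot_change
  if (is.null(pc)) {
    if (is.null(mappings))
      stop("pairs carry no prot_change and no mappings were given",
           call. = FALSE)
    key <- paste(pairs$human_accession, pairs$orthologue_accession)
    mkey <- paste(mappings$human_accession, mappings$orthologue_accession)
    pc <- mappings$prot_change[match(key, mkey)]
  }
  disc <- abs(pairs$pchembl_human - pairs$pchembl_orthologue)
  ok <- !is.na(pc) & !is.na(disc)
  n_excluded <- sum(!ok)
  pc <- pc[ok]; disc <- disc[ok]
  bin <- floor(pc / bin_width)
  per_bin <- do.call(rbind, lapply(split(seq_along(pc), bin), function(i)
    data.frame(bin_lo = bin_width * bin[i[1]],
               bin_hi = bin_width * (bin[i[1]] + 1),
               n = length(i),
               median_abs_discordance = stats::median(disc[i]))))
  rownames(per_bin) <- NULL
  trend <- if (length(pc) < 3 || stats::sd(pc) == 0) NA_real_
           else if (stats::sd(disc) == 0) 0   # flat discordance: no trend
           else stats::cor(pc, disc)^2
  list(per_bin = per_bin[order(per_bin$bin_lo), , drop = FALSE],
       trend_r_squared = trend,
       n_excluded_missing = n_excluded)
}
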