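#' Build the orthologue-aware training sets and audit reports
#'
#' Chains the curation, mapping, sampling and audit stages over a set of
#' in-memory input tables (the shape produced by
#' [generate_bioactivity_tables()] or by reading the standard dialects
#' with [read_bioactivity()] / [read_homologene()]):
#' structure standardization and filtering, active selection, label
#' conflict resolution, orthologue-to-human mapping with duplicate-SMILES
#' removal, the minimum-actives threshold, sphere-exclusion sampling of
#' putative inactives, and the conflict / concordance / chemical-space
#' audits.  Every stage logs its in/out counts.
#'
#' @param tables list with `chembl`, `pubchem`, `homologene` data.frames,
#'   a `library` data.frame (`compound_id`, `smiles`), and optionally
#'   `pairs` (paired affinities) and `target_classes`.
#' @param curation a [curation_config()].
#' @param sampling a [sampling_config()].
#' @param human_taxon taxon label of the reference species.
#' @return a `pipeline_build` list: merged `actives`, per-target
#'   `inactives`, fingerprint matrix `fps` (rows keyed by standardized
#'   SMILES), audit reports, merge/filter logs and stage counts.
#' @export
build_pipeline <- function(tables, curation = curation_config(),
                           sampling = sampling_config(),
                           human_taxon = "9606") {
  counts <- list()

  # -- structure standardization over every distinct raw SMILES ----------
  raw <- unique(c(tables$chembl$smiles, tables$pubchem$smiles,
                  tables$library$smiles))
  std <- standardize_structures(raw)
  std_map <- stats::setNames(std$smiles, std$input)
  counts$structures <- c(distinct = length(raw), rejected = sum(!std$ok))

  uniq <- unique(std$smiles[std$ok])
  props <- compound_properties(uniq)
  filt <- structure_filter(props, curation)
  pass_set <- uniq[filt$pass]
  counts$structure_filter <- c(checked = length(uniq),
                               failed = sum(!filt$pass))

  relabel <- function(df) {
    df$smiles <- unname(std_map[df$smiles])
    df[!is.na(df$smiles) & df$smiles %in% pass_set, , drop = FALSE]
  }
  chem <- relabel(tables$chembl)
  pub <- relabel(tables$pubchem)
  lib <- relabel(tables$library)
  lib <- lib[!duplicated(lib$smiles), , drop = FALSE]

  # -- active selection and inactive table -------------------------------
  sel <- select_actives(chem, curation)
  counts$actives <- c(input = nrow(chem), selected = nrow(sel$records),
                      rejected = nrow(sel$rejected))
  inact <- pub
  ikey <- paste(inact$smiles, inact$target_accession, sep = "\r")
  inact <- inact[!duplicated(ikey), , drop = FALSE]
  inact$label <- "inactive"
  counts$inactives <- c(input = nrow(pub), distinct = nrow(inact))

  mappings <- homologene_mappings(tables$homologene, human_taxon)

  # -- audits on the curated, pre-merge records --------------------------
  actives_all <- sel$records
  conflicts_fwd <- conflict_analysis(
    actives_all, inact, mappings, mapped_side = "orthologue",
    direction = "orthologue actives vs human inactives")
  conflicts_rev <- conflict_analysis(
    inact, actives_all, mappings, mapped_side = "human",
    direction = "human inactives vs orthologue actives")
  concordance <- if (!is.null(tables$pairs))
    concordance_analysis(tables$pairs) else NULL
  prot_change <- if (!is.null(tables$pairs))
    prot_change_binning(tables$pairs, mappings) else NULL

  res <- resolve_conflicting_labels(actives_all, inact)
  counts$label_conflicts_resolved <- res$n_conflicts

  # -- orthologue merge and minimum-actives threshold --------------------
  is_human <- actives_all$species == human_taxon
  merged <- merge_orthologue_actives(actives_all[is_human, , drop = FALSE],
                                     actives_all[!is_human, , drop = FALSE],
                                     mappings)
  mfilt <- apply_min_actives(merged$actives, curation$min_actives)
  human_only_counts <- table(merged$actives$target_accession[
    merged$actives$provenance == "human"])
  targets_before <- names(human_only_counts)[
    human_only_counts >= curation$min_actives]
  counts$targets <- c(before_orthologues = length(targets_before),
                      after_orthologues = length(mfilt$kept_targets),
                      newly_enabled = length(mfilt$newly_enabled))

  # -- fingerprints (one row per standardized structure) -----------------
  fp_smiles <- unique(c(mfilt$actives$smiles, res$inactives$smiles,
                        lib$smiles))
  fps <- fingerprint(fp_smiles, ids = fp_smiles)

  # -- per-target inactive sets (measured first, sphere-exclusion top-up)
  inactive_sets <- list()
  kept <- sort(mfilt$kept_targets)
  for (k in seq_along(kept)) {
    tgt <- kept[k]
    act <- mfilt$actives[mfilt$actives$target_accession == tgt, ,
                         drop = FALSE]
    meas <- res$inactives[res$inactives$target_accession == tgt, ,
                          drop = FALSE]
    active_fps <- fps[act$smiles, , drop = FALSE]
    rownames(active_fps) <- act$compound_id
    pool <- lib[!lib$compound_id %in% act$compound_id &
                  !lib$smiles %in% c(act$smiles, meas$smiles), ,
                drop = FALSE]
    pool_fps <- fps[pool$smiles, , drop = FALSE]
    rownames(pool_fps) <- pool$compound_id
    cfg <- sampling_config(ratio = sampling$ratio,
                           exclusion_tc = sampling$exclusion_tc,
                           seed = sampling$seed + k)
    inactive_sets[[tgt]] <- fill_inactives(
      act, meas, active_fps, pool_fps,
      pool_smiles = stats::setNames(pool$smiles, pool$compound_id),
      config = cfg)
  }

  # -- chemical-space audit: each target's orthologue actives against the
  # same target's human actives ------------------------------------------
  nn <- NULL
  nn_parts <- lapply(kept, function(tgt) {
    act <- mfilt$actives[mfilt$actives$target_accession == tgt, ,
                         drop = FALSE]
    o <- act[act$provenance != "human", , drop = FALSE]
    h <- act[act$provenance == "human", , drop = FALSE]
    if (!nrow(o) || !nrow(h)) return(NULL)
    qf <- fps[o$smiles, , drop = FALSE]
    rownames(qf) <- o$compound_id
    rf <- fps[unique(h$smiles), , drop = FALSE]
    nn_to_reference(qf, rf, groups = rep(tgt, nrow(o)))
  })
  nn_parts <- Filter(Negate(is.null), nn_parts)
  if (length(nn_parts)) {
    nn <- do.call(rbind, nn_parts)
    class(nn) <- c("nn_summary", "data.frame")
  }

  structure(list(actives = mfilt$actives,
                 inactive_sets = inactive_sets,
                 kept_targets = kept,
                 newly_enabled = mfilt$newly_enabled,
                 targets_before = targets_before,
                 fps = fps,
                 mappings = mappings,
                 merge_log = merged$log,
                 orphans = merged$orphans,
                 audits = list(conflicts_fwd = conflicts_fwd,
                               conflicts_rev = conflicts_rev,
                               concordance = concordance,
                               prot_change = prot_change,
                               nn = nn),
                 rejections = list(structures = std[!std$ok, , drop = FALSE],
                                   actives = sel$rejected),
                 counts = counts,
                 curation = curation, sampling = sampling,
                 human_taxon = human_taxon),
            class = "pipeline_build")
}

#' @export
print.pipeline_build <- function(x, ...) {
  cat("Orthologue-aware training-set build\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                paste(names(v), v, sep = "=", collapse = ", ")))
  }
  cat(sprintf("  modelled targets: %d (%d newly enabled by orthologues)\n",
              length(x$kept_targets), length(x$newly_enabled)))
  invisible(x)
}

#' Paired-arm time-series cross-validation for one target
#'
#' Evaluates the same chronological test windows under two training
#' regimes: the base arm trains on the windowed base records alone, the
#' augmented arm additionally receives every extra record strictly older
#' than the fold's test block (the orthologue actives).  Fold geometry,
#' test compounds and seeds are identical across arms, so differences are
#' attributable to the added training data.
#'
#' @param x,y,dates base records (fingerprints, labels, dates).
#' @param x_extra,y_extra,dates_extra additional training-only records.
#' @param config a [metric_config()].
#' @param seed RNG seed shared by both arms.
#' @param ... algorithm and hyper-parameters for [target_model()].
#' @return list with `before` and `after` per-fold metric tables.
#' @export
cv_paired_arms <- function(x, y, dates, x_extra, y_extra, dates_extra,
                           config = metric_config(), seed = 1L, ...) {
  y <- as_active(y); y_extra <- as_active(y_extra)
  folds <- time_series_folds(dates, config$n_splits)
  run_fold <- function(f, add_extra) {
    xtr <- x[f$train, , drop = FALSE]
    ytr <- y[f$train]
    if (add_extra && length(y_extra)) {
      ok <- dates_extra < min(dates[f$test])
      xtr <- rbind(xtr, x_extra[ok, , drop = FALSE])
      ytr <- c(ytr, y_extra[ok])
    }
    out <- data.frame(n_train = length(ytr), n_test = length(f$test),
                      precision = NA_real_, recall = NA_real_,
                      f1 = NA_real_, pr_auc = NA_real_, bedroc = NA_real_)
    if (sum(ytr) < 2 || sum(!ytr) < 2) return(out)
    fit <- target_model(xtr, ytr, seed = seed, ...)
    p <- predict(fit, x[f$test, , drop = FALSE])
    yte <- y[f$test]
    cm <- classification_metrics(p, yte, config$decision_threshold)
    out$precision <- cm$precision; out$recall <- cm$recall
    out$f1 <- cm$f1
    if (any(yte) && !all(yte)) {
      out$pr_auc <- pr_auc(p, yte)
      out$bedroc <- suppressWarnings(bedroc(p, yte, config$bedroc_alpha))
    }
    out
  }
  arm <- function(add_extra) {
    res <- do.call(rbind, lapply(folds, run_fold, add_extra = add_extra))
    res$fold <- seq_len(nrow(res))
    res
  }
  list(before = arm(FALSE), after = arm(TRUE))
}

#' Benchmark orthologue inclusion across the hyper-parameter grid
#'
#' For every modelled target, assembles the fingerprint design from a
#' [build_pipeline()] result (human actives and the shared inactive set
#' as the base arm; orthologue actives as the training-only extras) and
#' runs [cv_paired_arms()] for each algorithm / hyper-parameter setting.
#' Inactive records carry no meaningful assay dates, so they are assigned
#' dates interleaved through the target's active chronology, keeping
#' every fold's class mix representative.
#'
#' @param build a `pipeline_build`.
#' @param grid data.frame in the layout of [hyperparameter_grid()] (rows
#'   may be subset for speed).
#' @param config a [metric_config()].
#' @param seed base RNG seed.
#' @param targets optional subset of targets to benchmark.
#' @return list with `reports` (one [benchmark()] report per grid row)
#'   and `table` (the algorithm x hyper-parameter x arm summary).
#' @export
run_benchmark <- function(build, grid = hyperparameter_grid(),
                          config = metric_config(), seed = 1L,
                          targets = NULL) {
  stopifnot(inherits(build, "pipeline_build"))
  targets <- if (is.null(targets)) build$kept_targets
             else intersect(targets, build$kept_targets)
  designs <- lapply(targets, function(tgt) {
    act <- build$actives[build$actives$target_accession == tgt, ,
                         drop = FALSE]
    human <- act[act$provenance == "human", , drop = FALSE]
    ortho <- act[act$provenance != "human", , drop = FALSE]
    inact <- build$inactive_sets[[tgt]]
    if (nrow(human) < 2 || is.null(inact) || nrow(inact) == 0)
      return(NULL)
    hd <- sort(human$date)
    inact_dates <- rep(hd, length.out = nrow(inact))
    x <- build$fps[c(human$smiles, inact$smiles), , drop = FALSE]
    list(x = x,
         y = c(rep(TRUE, nrow(human)), rep(FALSE, nrow(inact))),
         dates = c(human$date, sort(inact_dates)),
         x_extra = build$fps[ortho$smiles, , drop = FALSE],
         y_extra = rep(TRUE, nrow(ortho)),
         dates_extra = ortho$date)
  })
  names(designs) <- targets
  designs <- Filter(Negate(is.null), designs)

  reports <- list()
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    alg <- grid$algorithm[g]
    args <- switch(alg,
                   random_forest = list(trees = grid$trees[g]),
                   bernoulli_nb = list(alpha = grid$alpha[g]),
                   linear_svm = list(cost = grid$cost[g]))
    hp_label <- paste(names(args), unlist(args), sep = "=")
    before <- list(); after <- list()
    for (tgt in names(designs)) {
      d <- designs[[tgt]]
      cv <- do.call(cv_paired_arms,
                    c(list(d$x, d$y, d$dates, d$x_extra, d$y_extra,
                           d$dates_extra, config = config, seed = seed,
                           algorithm = alg), args))
      before[[tgt]] <- cv$before
      after[[tgt]] <- cv$after
    }
    rep <- benchmark(before, after)
    key <- paste(alg, hp_label)
    reports[[key]] <- rep
    s <- rep$summary
    rows[[key]] <- data.frame(
      algorithm = alg, hyperparameter = hp_label,
      f1_before = s$f1_before[["median"]],
      f1_after = s$f1_after[["median"]],
      median_f1_delta = s$median_f1_delta,
      share_stable_or_improved = s$share_stable_or_improved_f1,
      bedroc_before = s$bedroc_before[["median"]],
      bedroc_after = s$bedroc_after[["median"]])
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(reports = reports, table = table)
}

#' Read / write a plain-text key=value run configuration
#'
#' Lines of `key = value`; blank lines and `#` comments ignored.  Values
#' round-trip as character; numeric keys are coerced by the consumer.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1],
                     call. = FALSE)
  stats::setNames(lapply(kv, function(p) trimws(p[3])),
                  vapply(kv, function(p) trimws(p[2]), ""))
}

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Run the build stage from a configuration
#'
#' Reads the input tables named by the configuration (`chembl`,
#' `pubchem`, `homologene`, `library`, optional `pairs`,
#' `target_classes`), runs [build_pipeline()] and writes the curated
#' tables, training sets, audit reports and a JSON manifest of stage
#' counts into `out_dir`.
#'
#' @param config named list (see [read_run_config()]) or path to a
#'   config file.
#' @return the `pipeline_build`, invisibly.
#' @export
run_build <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  need <- c("chembl", "pubchem", "homologene", "library", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (key in c("chembl", "pubchem", "homologene", "library"))
    if (!file.exists(config[[key]]))
      stop("input path for '", key, "' does not exist: ", config[[key]],
           call. = FALSE)
  tables <- list(
    chembl = read_bioactivity(config$chembl),
    pubchem = read_bioactivity(config$pubchem),
    homologene = utils::read.table(config$homologene, header = TRUE,
                                   sep = "\t", quote = "",
                                   stringsAsFactors = FALSE,
                                   na.strings = c("NA", "")),
    library = {
      parts <- strsplit(readLines(config$library), "\t", fixed = TRUE)
      data.frame(compound_id = vapply(parts, `[`, "", 2L),
                 smiles = vapply(parts, `[`, "", 1L),
                 stringsAsFactors = FALSE)
    })
  if (!is.null(config$pairs) && file.exists(config$pairs))
    tables$pairs <- utils::read.table(config$pairs, header = TRUE,
                                      sep = "\t", quote = "",
                                      stringsAsFactors = FALSE)
  cur <- curation_config(
    pchembl_active_min = as.numeric(config$pchembl_active_min %||% 5),
    min_actives = as.integer(config$min_actives %||% 10))
  samp <- sampling_config(
    ratio = as.numeric(config$ratio %||% 100),
    exclusion_tc = as.numeric(config$exclusion_tc %||% 0.424),
    seed = as.integer(config$seed %||% 1))
  build <- build_pipeline(tables, cur, samp)
  write_build_artifacts(build, config$out_dir)
  invisible(build)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_build_artifacts <- function(build, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(build$actives, file.path(out_dir, "actives.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  inact <- do.call(rbind, lapply(names(build$inactive_sets), function(t) {
    d <- build$inactive_sets[[t]]; d$target_accession <- t; d
  }))
  utils::write.table(inact, file.path(out_dir, "inactives.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  utils::write.table(build$audits$conflicts_fwd$per_mapping,
                     file.path(out_dir, "conflicts_ortho_vs_human.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(build$audits$conflicts_rev$per_mapping,
                     file.path(out_dir, "conflicts_human_vs_ortho.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(counts = build$counts,
                   kept_targets = build$kept_targets,
                   newly_enabled = build$newly_enabled,
                   conflict_totals_fwd = build$audits$conflicts_fwd$totals,
                   conflict_totals_rev = build$audits$conflicts_rev$totals)
  if (!is.null(build$audits$concordance)) {
    cc <- build$audits$concordance
    manifest$concordance <- list(
      n_pairs = cc$n_pairs, r_squared = cc$r_squared,
      median_abs_discordance = cc$median_abs_discordance,
      frac_both_active = cc$frac_both_active)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
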