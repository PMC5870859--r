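#' Specification for synthetic bioactivity fixtures
#'
#' Describes a self-contained synthetic study: a scaffold-clustered
#' compound library, ChEMBL-style human and orthologue actives,
#' PubChem-style inactives with a controlled rate of planted
#' active/inactive conflicts, paired human/orthologue affinity
#' measurements with controlled concordance noise, and a HomoloGene-style
#' mapping table.  Every output is a deterministic function of `seed`.
#'
#' Default rates mirror the magnitudes reported for the public
#' repositories: around 1.1% of orthologue bioactivities conflicting with
#' human inactives, paired affinities differing by a zero-mean error of
#' 0.75 pChEMBL units (median absolute discordance about 0.5), and
#' orthologue chemistry largely drawn from scaffolds absent from the
#' human training data.
#'
#' @param n_targets number of human targets.
#' @param n_human_actives human actives per (non-sparse) target.
#' @param n_ortho_actives orthologue actives per target.
#' @param n_sparse_targets targets given too few human actives to be
#'   modelled alone, so that only orthologue additions push them over the
#'   minimum-actives threshold.
#' @param ortho_species named probability vector of orthologue taxa
#'   (defaults: rat 10116, mouse 10090, bovine 9913).
#' @param conflict_rate probability that an orthologue active is planted
#'   as an inactive of the mapped human target.
#' @param concordance_sd standard deviation, in pChEMBL units, of the
#'   human-vs-orthologue affinity difference for paired measurements.
#' @param pair_rate fraction of orthologue actives also measured in human
#'   (forming the concordance pairs).
#' @param pchembl_mean,pchembl_sd affinity distribution of actives (values
#'   truncated at the 5.0 activity cut-off).
#' @param n_measured_inactives measured (screening) inactives per target.
#' @param test_novelty fraction of each target's human actives assigned
#'   the newest dates and drawn from the target's orthologue scaffold, so
#'   chronological test windows contain chemistry that orthologue
#'   training data can explain.
#' @param pool_size compound library size (max 1152 distinct structures).
#' @param date_span two dates bounding the record dates.
#' @param seed integer RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_targets = 12L, n_human_actives = 40L,
                         n_ortho_actives = 15L, n_sparse_targets = 2L,
                         ortho_species = c("10116" = 0.6, "10090" = 0.3,
                                           "9913" = 0.1),
                         conflict_rate = 0.011, concordance_sd = 0.75,
                         pair_rate = 0.6,
                         pchembl_mean = 6.4, pchembl_sd = 0.8,
                         n_measured_inactives = 5L, test_novelty = 0.3,
                         pool_size = 800L,
                         date_span = as.Date(c("2000-01-01",
                                               "2015-12-31")),
                         seed = 7L) {
  stopifnot(conflict_rate >= 0, conflict_rate <= 1,
            pair_rate >= 0, pair_rate <= 1,
            test_novelty >= 0, test_novelty <= 1,
            n_sparse_targets < n_targets, pool_size >= 10)
  structure(as.list(environment()), class = "fixture_spec")
}

# Drug-like scaffold bank: each template takes two aromatic substituents.
# The scaffold index is the library's cluster label.
FIXTURE_SCAFFOLDS <- c(
  "O=C(Nc1ccc(%s)cc1)c1ccc(%s)cc1",          # benzanilide
  "O=S(=O)(Nc1ccc(%s)cc1)c1ccc(%s)cc1",      # benzenesulfonanilide
  "c1cc(%s)ccc1-c1nc2cc(%s)ccc2[nH]1",       # 2-arylbenzimidazole
  "O=C(N1CCN(C(=O)c2ccc(%s)cc2)CC1)c1ccc(%s)cc1",  # diaroylpiperazine
  "c1cc(%s)ccc1Oc1ccc(%s)cc1",               # diphenyl ether
  "O=C(Oc1ccc(%s)cc1)c1ccc(%s)cc1",          # phenyl benzoate
  "c1cc(%s)ccc1-c1ccc(%s)nc1",               # arylpyridine
  "O=C(NCc1ccc(%s)cc1)c1ccc(%s)cc1")         # N-benzylbenzamide

FIXTURE_SUBSTITUENTS <- c("F", "Cl", "Br", "C", "CC", "OC", "OCC",
                          "N(C)C", "C(F)(F)F", "C#N", "O", "S(=O)(=O)C")

#' Generate the synthetic compound library
#'
#' Enumerates substituted drug-like scaffolds and draws a seeded sample.
#' All structures are single-fragment, neutral, carbon-based, free of
#' forbidden elements and inside the 100-1000 Da window, so they pass the
#' curation structure filter by construction.  Compounds sharing a
#' scaffold share a cluster label; intra-cluster fingerprint similarity
#' exceeds inter-cluster similarity on average.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with `compound_id`, `smiles`, `cluster`.
#' @export
generate_library <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  combos <- expand.grid(sub1 = FIXTURE_SUBSTITUENTS,
                        sub2 = FIXTURE_SUBSTITUENTS,
                        scaffold = seq_along(FIXTURE_SCAFFOLDS),
                        stringsAsFactors = FALSE)
  # scaffolds 4 (diaroylpiperazine) and 5 (diphenyl ether) are symmetric
  # under slot exchange; keep one ordering so every entry is a distinct
  # structure
  sym <- combos$scaffold %in% c(4L, 5L)
  combos <- combos[!(sym & combos$sub1 > combos$sub2), , drop = FALSE]
  if (spec$pool_size > nrow(combos))
    stop("pool_size exceeds the ", nrow(combos),
         " distinct structures the scaffold bank enumerates",
         call. = FALSE)
  smiles <- sprintf(FIXTURE_SCAFFOLDS[combos$scaffold], combos$sub1,
                    combos$sub2)
  keep <- withr::with_seed(spec$seed,
                           sample(nrow(combos), spec$pool_size))
  out <- data.frame(compound_id = sprintf("CPD%06d", seq_len(spec$pool_size)),
                    smiles = smiles[keep],
                    cluster = combos$scaffold[keep],
                    stringsAsFactors = FALSE)
  out
}

#' Generate the full set of synthetic input tables
#'
#' Produces, deterministically from the seed: a ChEMBL-style active table
#' (human plus orthologue measurements), a PubChem-style inactive table
#' with `conflict_rate` of the orthologue actives planted as human
#' inactives, a HomoloGene-style orthologue group table, the paired
#' human/orthologue affinity measurements, the compound library, and a
#' bookkeeping ledger holding every planted quantity (realized conflict
#' count, pair count, per-target compositions, target classes).
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `chembl`, `pubchem`, `homologene`, `pairs`,
#'   `library`, `target_classes` and `ledger`.
#' @export
generate_bioactivity_tables <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  lib <- generate_library(spec)
  withr::with_seed(spec$seed + 1L, generate_tables_impl(spec, lib))
}

generate_tables_impl <- function(spec, lib) {
  n_scaff <- length(FIXTURE_SCAFFOLDS)
  classes <- c("GPCR", "kinase", "NHR", "protease", "hydrolase",
               "ion channel", "transporter", "other enzyme")
  targets <- sprintf("HUM%03d", seq_len(spec$n_targets))
  target_classes <- data.frame(
    target_accession = targets,
    class = classes[(seq_len(spec$n_targets) - 1L) %% length(classes) + 1L],
    stringsAsFactors = FALSE)
  sparse <- seq_len(spec$n_sparse_targets)
  dates <- seq(spec$date_span[1], spec$date_span[2], by = "day")

  draw_pchembl <- function(n) {
    p <- spec$pchembl_mean + stats::rnorm(n, 0, spec$pchembl_sd)
    low <- p < 5.02
    p[low] <- 5.02 + stats::runif(sum(low), 0, 0.3)
    round(p, 2)
  }
  record <- function(compound, target, species, pchembl, date, source,
                     comment = NA_character_) {
    data.frame(compound_id = compound$compound_id,
               smiles = compound$smiles,
               target_accession = target, species = species,
               standard_value = if (all(is.na(pchembl))) NA_real_
                 else round(from_pchembl(pchembl, "nM"), 6),
               standard_units = "nM",
               standard_type = sample(c("Ki", "IC50", "EC50"),
                                      nrow(compound), replace = TRUE),
               assay_type = sample(c("binding", "functional"),
                                   nrow(compound), replace = TRUE,
                                   prob = c(0.7, 0.3)),
               confidence = sample(6:9, nrow(compound), replace = TRUE),
               activity_comment = comment,
               date = date, source = source,
               stringsAsFactors = FALSE)
  }

  chembl <- list(); pubchem <- list(); homolo <- list(); pairs <- list()
  ledger_rows <- list()
  n_conflicts_planted <- 0L

  for (i in seq_len(spec$n_targets)) {
    tgt <- targets[i]
    human_clusters <- ((i - 1L) %% n_scaff) + c(1L, 2L)
    human_clusters <- ((human_clusters - 1L) %% n_scaff) + 1L
    ortho_cluster <- ((i + 2L) %% n_scaff) + 1L
    species <- sample(names(spec$ortho_species), 1L,
                      prob = spec$ortho_species)
    ortho_acc <- sprintf("ORT%03d", i)

    n_h <- if (i %in% sparse) max(3L, spec$n_human_actives %/% 6L)
           else spec$n_human_actives
    # only every other target sees novel-scaffold chemistry in its human
    # (and hence test-window) data: orthologue inclusion helps those
    # targets, while the others keep orthologue chemistry fully disjoint
    # from human space, as the chemical-space audit expects
    n_novel <- if (i %% 2L == 0L) round(spec$test_novelty * n_h) else 0L
    base_pool <- lib[lib$cluster %in% human_clusters, , drop = FALSE]
    novel_pool <- lib[lib$cluster == ortho_cluster, , drop = FALSE]
    h_base <- base_pool[sample(nrow(base_pool),
                               min(n_h - n_novel, nrow(base_pool))), ]
    h_novel <- novel_pool[sample(nrow(novel_pool),
                                 min(n_novel, nrow(novel_pool))), ]

    # chronology: novel-scaffold chemistry appears last, so time-series
    # test windows contain structures that orthologue data can explain
    d_all <- sort(sample(dates, nrow(h_base) + nrow(h_novel)))
    chembl[[length(chembl) + 1L]] <-
      record(h_base, tgt, "9606", draw_pchembl(nrow(h_base)),
             utils::head(d_all, nrow(h_base)), "chembl")
    if (nrow(h_novel))
      chembl[[length(chembl) + 1L]] <-
        record(h_novel, tgt, "9606", draw_pchembl(nrow(h_novel)),
               utils::tail(d_all, nrow(h_novel)), "chembl")

    # orthologue measurements live in the novel scaffold; the orthologue
    # affinity is the human value plus concordance noise, and only
    # measurements at or above the activity cut-off become actives
    o_pool <- novel_pool[!novel_pool$compound_id %in%
                           h_novel$compound_id, , drop = FALSE]
    o_cmp <- o_pool[sample(nrow(o_pool),
                           min(spec$n_ortho_actives, nrow(o_pool))), ]
    o_h_pchembl <- draw_pchembl(nrow(o_cmp))
    o_pchembl <- round(o_h_pchembl +
                         stats::rnorm(nrow(o_cmp), 0, spec$concordance_sd),
                       2)
    chembl[[length(chembl) + 1L]] <-
      record(o_cmp, ortho_acc, species, o_pchembl,
             sample(dates, nrow(o_cmp)), "chembl")
    o_active <- o_pchembl >= 5

    # paired human measurement for a fraction of orthologue compounds
    paired <- stats::runif(nrow(o_cmp)) < spec$pair_rate
    if (any(paired))
      pairs[[length(pairs) + 1L]] <- data.frame(
        compound_id = o_cmp$compound_id[paired],
        human_accession = tgt, orthologue_accession = ortho_acc,
        pchembl_human = o_h_pchembl[paired],
        pchembl_orthologue = o_pchembl[paired],
        standard_units = "nM",
        standard_type = sample(c("Ki", "IC50"), sum(paired),
                               replace = TRUE),
        assay_type = sample(c("binding", "functional"), sum(paired),
                            replace = TRUE),
        stringsAsFactors = FALSE)

    # planted conflicts: orthologue *actives* duplicated as human
    # inactives (only actives can conflict after curation)
    confl <- o_active & stats::runif(nrow(o_cmp)) < spec$conflict_rate
    n_conflicts_planted <- n_conflicts_planted + sum(confl)
    if (any(confl))
      pubchem[[length(pubchem) + 1L]] <-
        record(o_cmp[confl, , drop = FALSE], tgt, "9606", NA_real_,
               sample(dates, sum(confl)), "pubchem", comment = "inactive")

    # background measured inactives, kept clear of every active structure
    # of this target pair so planted conflict counts stay exact
    used <- unique(c(h_base$compound_id, h_novel$compound_id,
                     o_cmp$compound_id))
    bg_pool <- lib[!lib$compound_id %in% used, , drop = FALSE]
    bg <- bg_pool[sample(nrow(bg_pool), spec$n_measured_inactives), ]
    pubchem[[length(pubchem) + 1L]] <-
      record(bg, tgt, "9606", NA_real_, sample(dates, nrow(bg)),
             "pubchem", comment = "inactive")

    homolo[[length(homolo) + 1L]] <- data.frame(
      group_id = i,
      taxon_id = c("9606", species),
      accession = c(tgt, ortho_acc),
      gene_symbol = sprintf("GENE%03d", i),
      prot_change = c(NA_real_, round(stats::runif(1, 0, 0.45), 3)),
      stringsAsFactors = FALSE)

    ledger_rows[[i]] <- data.frame(
      target_accession = tgt, orthologue_accession = ortho_acc,
      species = species, sparse = i %in% sparse,
      n_human = nrow(h_base) + nrow(h_novel),
      n_ortho = sum(o_active), n_conflicts = sum(confl),
      n_pairs = sum(paired),
      n_measured_inactives = nrow(bg),
      human_clusters = paste(human_clusters, collapse = "+"),
      ortho_cluster = ortho_cluster,
      stringsAsFactors = FALSE)
  }

  chembl <- do.call(rbind, chembl)
  pubchem <- do.call(rbind, pubchem)
  chembl$pchembl <- ifelse(is.na(chembl$standard_value), NA_real_,
                           to_pchembl(chembl$standard_value, "nM"))
  pubchem$pchembl <- NA_real_
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  ledger <- do.call(rbind, ledger_rows)
  rownames(chembl) <- rownames(pubchem) <- rownames(ledger) <- NULL

  list(chembl = chembl, pubchem = pubchem,
       homologene = do.call(rbind, homolo),
       pairs = pairs, library = lib,
       target_classes = target_classes,
       ledger = list(per_target = ledger,
                     n_conflicts_planted = n_conflicts_planted,
                     n_ortho_total = sum(ledger$n_ortho),
                     n_pairs_total = sum(ledger$n_pairs),
                     conflict_rate = spec$conflict_rate,
                     concordance_sd = spec$concordance_sd))
}

#' Write fixture tables to a directory in their standard dialects
#'
#' @param tables output of [generate_bioactivity_tables()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bioactivity(tables$chembl, file.path(dir, "chembl_like.tsv"))
  write_bioactivity(tables$pubchem, file.path(dir, "pubchem_like.tsv"))
  utils::write.table(tables$homologene,
                     file.path(dir, "homologene_like.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  utils::write.table(tables$pairs, file.path(dir, "paired_affinities.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  writeLines(paste(tables$library$smiles, tables$library$compound_id,
                   sep = "\t"),
             file.path(dir, "library.smi"))
  utils::write.table(tables$target_classes,
                     file.path(dir, "target_classes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
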