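make_mappings <- function(human, ortho, species = "10116",
                          prot_change = NA_real_) {
  data.frame(group_id = seq_along(human), human_accession = human,
             orthologue_accession = ortho,
             orthologue_species = rep_len(species, length(human)),
             prot_change = rep_len(prot_change, length(human)),
             stringsAsFactors = FALSE)
}

test_that("homologene tables parse into human-orthologue pairs", {
  df <- data.frame(group_id = c(1, 1, 1, 2, 2),
                   taxon_id = c("9606", "10116", "10090", "9606", "9913"),
                   accession = c("H1", "R1", "M1", "H2", "B2"),
                   gene_symbol = "G",
                   prot_change = c(NA, 0.05, 0.1, NA, 0.3))
  m <- homologene_mappings(df)
  expect_equal(nrow(m), 3)
  expect_setequal(m$orthologue_accession, c("R1", "M1", "B2"))
  expect_equal(m$human_accession[m$orthologue_accession == "B2"], "H2")
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_homologene(path), m)
  df$prot_change[2] <- 1.4
  expect_error(homologene_mappings(df), "prot_change")
})

test_that("orthologue merge removes duplicate SMILES and keeps human
           provenance", {
  human <- make_records(c("CCO", "CCN"), "H1")
  maps <- make_mappings("H1", "R1")
  # empty orthologue table: identity
  m0 <- merge_orthologue_actives(human, human[0, ], maps)
  expect_equal(nrow(m0$actives), 2)
  expect_true(all(m0$actives$provenance == "human"))
  # 3 orthologue actives, 1 sharing a structure with human: 2 added
  ortho <- make_records(c("CCO", "CCC", "CCF"), "R1", species = "10116")
  m1 <- merge_orthologue_actives(human, ortho, maps)
  expect_equal(nrow(m1$actives), 4)
  added <- m1$actives[m1$actives$provenance != "human", ]
  expect_setequal(added$smiles, c("CCC", "CCF"))
  expect_true(all(added$target_accession == "H1"))
  expect_true(all(added$provenance == "orthologue:10116"))
  expect_equal(m1$log$n_added, 2)
  expect_equal(m1$log$n_duplicate, 1)
  # set-difference oracle
  expect_setequal(added$smiles, setdiff(ortho$smiles, human$smiles))
  # unmapped accession: skipped and logged
  lost <- make_records("CCCl", "RX", species = "10116")
  m2 <- merge_orthologue_actives(human, lost, maps)
  expect_equal(nrow(m2$actives), 2)
  expect_equal(m2$orphans$accession, "RX")
  expect_equal(m2$orphans$n_records, 1)
})

test_that("the minimum-actives threshold flags newly enabled targets", {
  mk <- function(n_h, n_o, tgt) {
    h <- make_records(sprintf("H%s%02d", tgt, seq_len(n_h)), tgt)
    h$provenance <- "human"
    if (n_o == 0) return(h)
    o <- make_records(sprintf("O%s%02d", tgt, seq_len(n_o)), tgt)
    o$provenance <- "orthologue:10116"
    rbind(h, o)
  }
  acts <- rbind(mk(9, 0, "T9"), mk(10, 0, "T10"), mk(6, 4, "T64"))
  res <- apply_min_actives(acts, 10)
  expect_setequal(res$kept_targets, c("T10", "T64"))
  expect_equal(res$dropped_targets, "T9")
  expect_equal(res$newly_enabled, "T64")
  expect_false("T10" %in% res$newly_enabled)
})

test_that("coverage summary computes per-class counts and change", {
  classes <- data.frame(target_accession = sprintf("T%02d", 1:16),
                        class = rep(c("A", "B"), c(11, 5)))
  before <- sprintf("T%02d", c(1:10, 12:16))   # A: 10, B: 5
  after <- sprintf("T%02d", c(1:11, 12:16))    # A: 11, B: 5
  cov <- coverage_summary(before, after, classes)
  a <- cov$per_class[cov$per_class$class == "A", ]
  b <- cov$per_class[cov$per_class$class == "B", ]
  expect_equal(a$pct_change, 10)
  expect_equal(b$pct_change, 0)
  # identical arms: all zero
  cov0 <- coverage_summary(before, before, classes)
  expect_true(all(cov0$per_class$pct_change == 0))
  # share of augmented models: simple ratio
  cov2 <- coverage_summary(before, after, classes,
                           augmented_targets = after[1:8])
  expect_equal(cov2$share_augmented, 8 / 16)
  # unknown classes bucket as "other"
  cov3 <- coverage_summary("ZZZ", "ZZZ", classes)
  expect_true("other" %in% cov3$per_class$class)
})

test_that("conflict analysis counts planted conflicts exactly,
           mapping-level", {
  maps <- make_mappings(c("H1", "H2"), c("R1", "R2"))
  # disjoint compound sets: zero conflicts, 100% compatible
  act <- make_records(sprintf("A%02d", 1:10), "R1", species = "10116")
  ina <- make_records(sprintf("B%02d", 1:10), "H1")
  rep0 <- conflict_analysis(act, ina, maps)
  expect_equal(rep0$totals$n_conflicting, 0)
  expect_equal(rep0$totals$compatibility_pct, 100)
  # planted conflicts across two mappings vs a brute-force join
  set.seed(17)
  act2 <- rbind(
    make_records(sprintf("S%03d", 1:60), "R1", species = "10116"),
    make_records(sprintf("S%03d", 101:140), "R2", species = "10116"))
  confl1 <- sprintf("S%03d", sample(1:60, 9))
  confl2 <- sprintf("S%03d", sample(101:140, 4))
  ina2 <- rbind(make_records(c(confl1, "ZZZ1"), "H1"),
                make_records(c(confl2, "ZZZ2"), "H2"))
  rep1 <- conflict_analysis(act2, ina2, maps)
  expect_equal(rep1$totals$n_mapped, 100)
  expect_equal(rep1$totals$n_conflicting, 13)
  per <- rep1$per_mapping
  expect_equal(per$n_conflicting[per$orthologue_accession == "R1"], 9)
  expect_equal(per$n_conflicting[per$orthologue_accession == "R2"], 4)
  # brute-force smiles-join oracle over mapping pairs
  brute <- 0
  for (k in seq_len(nrow(maps))) {
    a <- act2$smiles[act2$target_accession ==
                       maps$orthologue_accession[k]]
    b <- ina2$smiles[ina2$target_accession == maps$human_accession[k]]
    brute <- brute + length(intersect(a, b))
  }
  expect_equal(rep1$totals$n_conflicting, brute)
  # empty mapping table: empty report
  repE <- conflict_analysis(act2, ina2, maps[0, ])
  expect_equal(repE$totals$n_mapped, 0)
})

test_that("compatibility statistics are invariant under row permutation
           and species relabeling", {
  maps <- make_mappings(c("H1", "H2"), c("R1", "R2"),
                        species = c("10116", "10090"))
  act <- rbind(make_records(sprintf("S%02d", 1:20), "R1",
                            species = "10116"),
               make_records(sprintf("S%02d", 21:35), "R2",
                            species = "10090"))
  ina <- make_records(sprintf("S%02d", c(3, 7, 25)),
                      c("H1", "H1", "H2"))
  base <- conflict_analysis(act, ina, maps)
  perm <- conflict_analysis(act[sample(nrow(act)), ],
                            ina[c(3, 1, 2), ], maps)
  expect_equal(perm$totals, base$totals)
  act$species <- "relabeled"
  relab <- conflict_analysis(act, ina, maps)
  expect_equal(relab$totals, base$totals)
})

test_that("concordance reports squared Pearson, median discordance and
           both-active fraction", {
  # identical paired values
  p0 <- data.frame(pchembl_human = c(5, 6, 7, 8),
                   pchembl_orthologue = c(5, 6, 7, 8))
  c0 <- concordance_analysis(p0)
  expect_equal(c0$r_squared, 1)
  expect_equal(c0$median_abs_discordance, 0)
  expect_equal(c0$frac_both_active, 1)
  # closed-form Pearson on (5,7),(6,6),(7,5)
  p1 <- data.frame(pchembl_human = c(5, 6, 7),
                   pchembl_orthologue = c(7, 6, 5))
  h <- c(5, 6, 7); o <- c(7, 6, 5)
  r_closed <- sum((h - mean(h)) * (o - mean(o))) /
    sqrt(sum((h - mean(h))^2) * sum((o - mean(o))^2))
  expect_equal(concordance_analysis(p1)$r_squared, r_closed^2)
  # groups with < 3 pairs report NA, not zero
  p2 <- data.frame(pchembl_human = c(5, 6, 7, 8, 5),
                   pchembl_orthologue = c(5.5, 6, 6.5, 8, 5),
                   standard_units = c("nM", "nM", "nM", "uM", "uM"),
                   standard_type = "Ki", assay_type = "binding")
  c2 <- concordance_analysis(p2)
  small <- c2$per_group[grep("uM", c2$per_group$group), ]
  expect_true(is.na(small$r_squared))
})

test_that("both-active fraction is monotone non-increasing in the
           cut-off", {
  set.seed(5)
  p <- data.frame(pchembl_human = rnorm(200, 6, 1),
                  pchembl_orthologue = rnorm(200, 6, 1))
  fr <- vapply(c(4, 5, 6, 7), function(ct)
    concordance_analysis(p, activity_cutoff = ct)$frac_both_active, 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("protein-change binning recovers planted medians and a flat
           trend reads zero", {
  # two bins with planted medians 0.5 and 1.0
  p <- data.frame(
    pchembl_human = c(6, 6, 6, 7, 7, 7),
    pchembl_orthologue = c(6.4, 6.5, 6.6, 7.9, 8.0, 8.1),
    prot_change = c(0.05, 0.06, 0.07, 0.15, 0.16, 0.17))
  out <- prot_change_binning(p, bin_width = 0.1)
  expect_equal(out$per_bin$median_abs_discordance, c(0.5, 1.0))
  expect_equal(out$per_bin$n, c(3, 3))
  # constant discordance across bins: no trend
  p2 <- p
  p2$pchembl_orthologue <- p2$pchembl_human + 0.5
  expect_equal(prot_change_binning(p2, bin_width = 0.1)$trend_r_squared, 0)
  # missing prot_change pairs are excluded and counted
  p3 <- p
  p3$prot_change[2] <- NA
  expect_equal(prot_change_binning(p3,
                                   bin_width = 0.1)$n_excluded_missing, 1)
  # prot_change can be resolved through the mapping table
  p4 <- p[, 1:2]
  p4$human_accession <- "H1"; p4$orthologue_accession <- "R1"
  maps <- make_mappings("H1", "R1", prot_change = 0.25)
  out4 <- prot_change_binning(p4, maps, bin_width = 0.1)
  expect_equal(out4$per_bin$bin_lo, 0.2)
})
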