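test_that("pChEMBL conversion matches -log10 molar and inverts", {
  expect_equal(to_pchembl(10, "uM"), 5)
  expect_equal(to_pchembl(1, "nM"), 9)
  expect_equal(to_pchembl(50, "nM"), -log10(5e-8))
  expect_equal(to_pchembl(50, "nM"), 7.301, tolerance = 1e-3)
  # round trip to tight relative tolerance across magnitudes
  v <- c(0.3, 1, 50, 12000)
  expect_equal(from_pchembl(to_pchembl(v, "nM"), "nM"), v,
               tolerance = 1e-9)
  expect_error(to_pchembl(10, "mg/kg"), "mg/kg")
  expect_error(to_pchembl(-1, "nM"), "positive")
})

test_that("structure standardization keeps the largest fragment and
           neutralizes", {
  res <- standardize_structures(c("c1ccccc1C(=O)[O-].[Na+]",
                                  "CCO", "not_a_smiles"))
  # sodium benzoate -> benzoic acid: counter-ion dropped, acid neutralized
  expect_true(res$ok[1])
  p <- compound_properties(res$smiles[1])
  expect_equal(p$formula, "C7H6O2")
  expect_false(grepl("Na", res$smiles[1]))
  expect_false(grepl("-", res$smiles[1], fixed = TRUE))
  # parse failures are reported, never dropped
  expect_false(res$ok[3])
  expect_match(res$reason[3], "unparseable")
  expect_equal(nrow(res), 3)
})

test_that("standardization is idempotent on a generated library", {
  lib <- generate_library(fixture_spec(pool_size = 60, seed = 3))
  once <- standardize_structures(lib$smiles)
  expect_true(all(once$ok))
  twice <- standardize_structures(once$smiles)
  expect_identical(twice$smiles, once$smiles)
})

test_that("structure filter applies carbon, element and weight rules in
           order", {
  cfg <- curation_config()
  p <- compound_properties(c("CCO", "c1ccccc1I"))
  f <- structure_filter(p, cfg)
  expect_false(f$pass[1])              # ethanol: MW ~46
  expect_match(f$reason[1], "weight")
  expect_true(f$pass[2])               # iodobenzene: I (Z=53) is allowed
  # iron (Z=26) lands in the first forbidden interval
  fe <- data.frame(smiles = "synthetic", formula = "C10H10Fe", mw = 186.03,
                   n_heavy = 11, elements = I(list(c(6L, 26L))))
  ffe <- structure_filter(fe, cfg)
  expect_false(ffe$pass)
  expect_match(ffe$reason, "forbidden element")
  # carbon rule precedes everything
  water <- data.frame(smiles = "O", formula = "H2O", mw = 18,
                      n_heavy = 1, elements = I(list(8L)))
  expect_match(structure_filter(water, cfg)$reason, "carbon")
})

test_that("structure filter agrees with a brute-force atom-scan oracle", {
  cfg <- curation_config()
  lib <- generate_library(fixture_spec(pool_size = 150, seed = 5))
  std <- standardize_structures(lib$smiles)
  props <- compound_properties(std$smiles)
  got <- structure_filter(props, cfg)
  oracle <- vapply(seq_len(nrow(props)), function(i) {
    z <- props$elements[[i]]
    if (!any(z == 6)) return(FALSE)
    for (zz in z)
      if ((zz >= 21 && zz <= 32) || (zz >= 36 && zz <= 52) || zz >= 54)
        return(FALSE)
    props$mw[i] >= 100 && props$mw[i] <= 1000
  }, TRUE)
  expect_identical(got$pass, oracle)
})

test_that("active selection applies affinity, comment and confidence
           rules at their boundaries", {
  cfg <- curation_config()
  recs <- rbind(
    make_records("CCO", "T1", pchembl = 5.0, confidence = 6),
    make_records("CCN", "T1", pchembl = 4.99, confidence = 9),
    make_records("CCC", "T1", pchembl = NA,
                 activity_comment = "active", confidence = 7),
    make_records("CCF", "T1", pchembl = 8, confidence = 5),
    make_records("CCI", "T1", pchembl = 8, assay_type = "other"),
    make_records("CCBr", NA_character_, pchembl = 8))
  out <- select_actives(recs, cfg)
  expect_setequal(out$records$smiles, c("CCO", "CCC"))
  expect_equal(nrow(out$rejected), 4)
  expect_match(out$rejected$reason[out$rejected$smiles == "CCN"],
               "threshold")
  expect_match(out$rejected$reason[out$rejected$smiles == "CCF"],
               "confidence")
  expect_match(out$rejected$reason[is.na(out$rejected$smiles) |
                                     out$rejected$smiles == "CCBr"][1],
               "accession")
})

test_that("duplicate measurements collapse to the earliest date and the
           result is row-order invariant", {
  recs <- rbind(
    make_records("CCO", "T1", pchembl = 6,
                 date = as.Date("2012-05-01")),
    make_records("CCO", "T1", pchembl = 7,
                 date = as.Date("2004-03-01")),
    make_records("CCO", "T1", pchembl = 8,
                 date = as.Date("2009-01-01")),
    make_records("CCN", "T1", pchembl = 6))
  out <- select_actives(recs)$records
  expect_equal(nrow(out), 2)
  expect_equal(out$date[out$smiles == "CCO"], as.Date("2004-03-01"))
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    alt <- select_actives(recs[perm, ])$records
    expect_setequal(paste(alt$smiles, alt$date),
                    paste(out$smiles, out$date))
  }
})

test_that("label conflicts resolve in favour of the curated active
           source", {
  actives <- make_records(c("CCO", "CCN"), "T1")
  inactives <- make_records(c("CCO", "CCC", "CCF"), "T1")
  res <- resolve_conflicting_labels(actives, inactives)
  expect_equal(res$n_conflicts, 1)
  expect_setequal(res$inactives$smiles, c("CCC", "CCF"))
  # disjoint tables: union preserved, zero conflicts
  res2 <- resolve_conflicting_labels(make_records("CCO", "T1"),
                                     make_records("CCO", "T2"))
  expect_equal(res2$n_conflicts, 0)
  expect_equal(nrow(res2$inactives), 1)
  # k planted conflicts resolved exactly, against a brute-force count
  set.seed(9)
  a <- make_records(sprintf("S%02d", 1:30),
                    target = sample(c("T1", "T2"), 30, replace = TRUE))
  planted <- sample(30, 7)
  i <- make_records(a$smiles[planted], a$target_accession[planted])
  i <- rbind(i, make_records(sprintf("X%02d", 1:10), "T1"))
  res3 <- resolve_conflicting_labels(a, i)
  brute <- sum(paste(i$smiles, i$target_accession) %in%
                 paste(a$smiles, a$target_accession))
  expect_equal(res3$n_conflicts, 7)
  expect_equal(nrow(i) - nrow(res3$inactives), brute)
})

test_that("bioactivity tables round-trip through the TSV dialect with
           derived pChEMBL", {
  recs <- make_records(c("CCO", "CCN"), "T1")
  recs$standard_value <- c(1000, 10)   # nM
  recs$pchembl <- NULL
  path <- tempfile(fileext = ".tsv")
  write_bioactivity(recs, path)
  back <- read_bioactivity(path)
  expect_equal(back$pchembl, c(6, 8))
  expect_equal(back$smiles, recs$smiles)
  expect_error(read_bioactivity({
    p <- tempfile(); writeLines("a\tb\n1\t2", p); p
  }), "missing columns")
})
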