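# Shared builders for the test suite.  Everything is generated in code
# under fixed seeds; no fixture files.

# deterministic random binary fingerprints
random_fps <- function(n, width = 64, density = 0.25, seed = 1,
                       prefix = "fp") {
  m <- withr::with_seed(seed,
    matrix(as.integer(stats::runif(n * width) < density), n, width))
  rownames(m) <- sprintf("%s%04d", prefix, seq_len(n))
  m
}

# independent double-loop nearest-neighbour oracle
brute_force_nn <- function(q, r, exclude_same_id = TRUE) {
  vapply(seq_len(nrow(q)), function(i) {
    best <- -Inf
    for (j in seq_len(nrow(r))) {
      if (exclude_same_id && !is.null(rownames(q)) &&
          !is.null(rownames(r)) && rownames(q)[i] == rownames(r)[j]) next
      inter <- sum(q[i, ] & r[j, ])
      uni <- sum(q[i, ] | r[j, ])
      best <- max(best, if (uni == 0) 1 else inter / uni)
    }
    if (is.finite(best)) best else NA_real_
  }, 0)
}

# minimal bioactivity record table in the curation schema
make_records <- function(smiles, target, species = "9606",
                         pchembl = 6, confidence = 8,
                         assay_type = "binding",
                         activity_comment = NA_character_,
                         date = as.Date("2010-01-01"),
                         compound_id = NULL) {
  n <- length(smiles)
  data.frame(compound_id = if (is.null(compound_id))
    sprintf("C%04d", seq_len(n)) else compound_id,
    smiles = smiles,
    target_accession = rep_len(target, n),
    species = rep_len(species, n),
    standard_value = NA_real_, standard_units = "nM",
    standard_type = "Ki",
    assay_type = rep_len(assay_type, n),
    confidence = rep_len(confidence, n),
    activity_comment = rep_len(activity_comment, n),
    date = rep_len(date, n),
    source = "test",
    pchembl = rep_len(pchembl, n),
    stringsAsFactors = FALSE)
}

# linearly separable fingerprint toy: actives carry a marker-bit block
separable_toy <- function(n_active = 20, n_inactive = 60, width = 64,
                          seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(as.integer(stats::runif((n_active + n_inactive) * width)
                           < 0.15),
                n_active + n_inactive, width)
    x[seq_len(n_active), 1:6] <- 1L
    x[-seq_len(n_active), 1:6] <- 0L
    x[-seq_len(n_active), 7:12] <- 1L
  })
  list(x = x, y = c(rep(TRUE, n_active), rep(FALSE, n_inactive)))
}
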