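#' Settings for sphere-exclusion sampling of putative inactives
#'
#' @param ratio inactives sought per active (default 100:1).
#' @param exclusion_tc Tanimoto radius of the exclusion spheres: pool
#'   compounds with nearest-neighbour similarity to any active at or above
#'   this value are ineligible.  The default 0.424 is the 95% NN-similarity
#'   radius reported for ChEMBL actives at human targets; it is a knob,
#'   not a constant.
#' @param seed RNG seed making the sample deterministic.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(ratio = 100, exclusion_tc = 0.424, seed = 1L) {
  stopifnot(ratio >= 1, exclusion_tc > 0, exclusion_tc <= 1)
  structure(list(ratio = ratio, exclusion_tc = exclusion_tc,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Sample putative inactives by sphere exclusion
#'
#' Every pool compound within Tanimoto `exclusion_tc` of any active is
#' excluded; the sample is a seeded uniform draw from the surviving pool.
#' The sample size is `ratio * n_actives - n_measured_inactives`, capped
#' at the eligible pool size (and at zero from below).  Given the same
#' seed the sample is identical across runs.
#'
#' @param active_fps binary fingerprint matrix of the target's actives
#'   (row names are compound ids).
#' @param pool_fps binary fingerprint matrix of the candidate pool,
#'   disjoint from the actives on compound id.
#' @param config a [sampling_config()].
#' @param n_measured_inactives measured inactives already available; the
#'   sample only tops up the difference.
#' @return character vector of sampled pool compound ids (possibly empty,
#'   with a warning when the pool is empty).
#' @export
sphere_exclusion_sample <- function(active_fps, pool_fps,
                                    config = sampling_config(),
                                    n_measured_inactives = 0L) {
  stopifnot(inherits(config, "sampling_config"))
  if (nrow(active_fps) == 0L)
    stop("no actives: exclusion spheres are undefined", call. = FALSE)
  if (nrow(pool_fps) == 0L) {
    warning("empty candidate pool; no inactives sampled")
    return(character(0))
  }
  nn <- apply(tanimoto_matrix(pool_fps, active_fps), 1L, max)
  eligible <- rownames(pool_fps)[nn < config$exclusion_tc]
  want <- max(0L, ceiling(config$ratio * nrow(active_fps)) -
                n_measured_inactives)
  k <- min(want, length(eligible))
  if (k == 0L) return(character(0))
  withr::with_seed(config$seed, sample(eligible)[seq_len(k)])
}

#' Top a training set up with sampled putative inactives
#'
#' Measured inactives are used first; when they fall short of the
#' configured active:inactive ratio the remainder is drawn by
#' [sphere_exclusion_sample()] and tagged with provenance `"sampled"`.
#'
#' @param actives data.frame of the target's active records (with
#'   `compound_id` and `smiles`).
#' @param measured_inactives data.frame of measured inactive records (may
#'   have zero rows); tagged with provenance `"measured"`.
#' @param active_fps,pool_fps fingerprints of the actives and of the
#'   candidate pool (pool row names are compound ids, with a `smiles`
#'   attribute-free lookup supplied via `pool_smiles`).
#' @param pool_smiles named character vector mapping pool compound ids to
#'   SMILES.
#' @param config a [sampling_config()].
#' @return data.frame of inactive training records with columns
#'   `compound_id`, `smiles`, `provenance`.
#' @export
fill_inactives <- function(actives, measured_inactives, active_fps,
                           pool_fps, pool_smiles = NULL,
                           config = sampling_config()) {
  measured <- if (is.null(measured_inactives) ||
                  nrow(measured_inactives) == 0L)
    data.frame(compound_id = character(0), smiles = character(0))
  else data.frame(compound_id = measured_inactives$compound_id,
                  smiles = measured_inactives$smiles,
                  stringsAsFactors = FALSE)
  measured$provenance <- rep("measured", nrow(measured))
  ids <- sphere_exclusion_sample(active_fps, pool_fps, config,
                                 n_measured_inactives = nrow(measured))
  sampled <- data.frame(compound_id = ids,
                        smiles = if (is.null(pool_smiles))
                          NA_character_ else unname(pool_smiles[ids]),
                        provenance = rep("sampled", length(ids)),
                        stringsAsFactors = FALSE)
  out <- rbind(measured, sampled)
  rownames(out) <- NULL
  out
}
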