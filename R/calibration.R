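#' Preprocess a cohort and stack its seed-FC maps
#'
#' Convenience wrapper running [preprocess_subject()], [seed_series()] and
#' [fc_zmap()] for every subject of an in-memory cohort.
#'
#' @param cohort a `synthetic_cohort` (or any list with `subjects`,
#'   `atlas`).
#' @param seed_source "bilateral", "left" or "right".
#' @param preproc a [preproc_config()].
#' @return a map stack as returned by [stack_fc_maps()].
#' @export
cohort_fc_stack <- function(cohort, seed_source = "bilateral",
                            preproc = preproc_config()) {
  zm <- lapply(cohort$subjects, function(s) {
    b <- preprocess_subject(s$bold, s$motion, cohort$atlas, preproc)
    fc_zmap(b, seed_series(b, cohort$atlas, seed_source),
            analysis_mask(cohort$atlas))
  })
  stack_fc_maps(zm)
}

#' Desk-scale null-cohort configuration
#'
#' The reference null condition for family-wise-error calibration: 40
#' subjects from 3 sites on a 16^3 grid (3 mm voxels, TR 2.2 s), 120
#' volumes, the default planted baseline couplings, but every age slope
#' set to zero (no age effect anywhere, including interhemispheric).
#'
#' @param rng_seed integer seed for this cohort.
#' @return a [simulation_config()].
#' @export
null_cohort_config <- function(rng_seed) {
  simulation_config(
    n_subjects = 40L, n_volumes = 120L,
    effects = list(effect_spec(10L, 0.40, 0), effect_spec(11L, 0.13, 0),
                   effect_spec(12L, 0.08, 0), effect_spec(13L, -0.08, 0)),
    lr_age_slope = 0, rng_seed = rng_seed)
}

#' Empirical FWE calibration on null cohorts
#'
#' Simulates independent null cohorts ([null_cohort_config()]), runs the
#' full pipeline (preprocessing, bilateral-seed FC, group GLM with
#' age/sex/site covariates, permutation cluster-level correction on the
#' positive-FC/age-decrease conjunction), and reports per cohort whether
#' any cluster was declared significant. Under the null the fraction of
#' positive cohorts estimates the realized family-wise error rate, to be
#' compared against `cluster_alpha`.
#'
#' @param n_cohorts number of independent null cohorts.
#' @param n_perm permutations per cohort (default 500).
#' @param rng_seed root seed; per-cohort streams are derived from it.
#' @param cluster_alpha cluster-level significance level (default 0.05).
#' @param connectivity cluster connectivity (default 26).
#' @return list: `any_significant` (logical per cohort), `fwe` (the
#'   fraction), `n_cohorts`.
#' @export
fwe_calibration <- function(n_cohorts = 200L, n_perm = 500L, rng_seed = 1L,
                            cluster_alpha = 0.05, connectivity = 26L) {
  any_sig <- vapply(seq_len(n_cohorts), function(i) {
    cfg <- null_cohort_config(derive_seed(rng_seed, "null-cohort", i))
    cohort <- simulate_cohort(cfg)
    stack <- cohort_fc_stack(cohort)
    design <- build_group_design(cohort$phenotypes)
    cs <- permutation_cluster_fwe(
      stack, design, contrast_pair("pos_age_decrease"),
      n_perm = n_perm, cluster_alpha = cluster_alpha,
      connectivity = connectivity,
      rng_seed = derive_seed(rng_seed, "null-perm", i))
    any(cs$significant)
  }, logical(1L))
  list(any_significant = any_sig, fwe = mean(any_sig), n_cohorts = n_cohorts)
}

#' Detection power for a planted age-related coupling decline
#'
#' Replicates a cohort carrying the default effects (including the
#' 27-voxel region whose coupling is `baseline_r` at the mean age and
#' declines by `age_slope` per year) and reports how often the pipeline
#' recovers it: a significant (p_fwe < `cluster_alpha`) cluster of the
#' positive-FC/age-decrease conjunction overlapping the planted region.
#'
#' @param n_replicates number of independent cohorts.
#' @param n_subjects subjects per cohort (default 80).
#' @param n_volumes BOLD series length (default 120).
#' @param baseline_r,age_slope planted coupling at the cohort mean age
#'   and its change per year (defaults 0.13 and -0.002).
#' @param n_perm permutations per cohort (default 500).
#' @param rng_seed root seed.
#' @param cluster_alpha cluster-level significance level (default 0.05).
#' @return list: `detected` (logical per replicate), `power` (the
#'   fraction), `n_replicates`.
#' @export
power_planted_decline <- function(n_replicates = 50L, n_subjects = 80L,
                                  n_volumes = 120L, baseline_r = 0.13,
                                  age_slope = -0.002, n_perm = 500L,
                                  rng_seed = 1L, cluster_alpha = 0.05) {
  detected <- vapply(seq_len(n_replicates), function(i) {
    cfg <- simulation_config(
      n_subjects = n_subjects, n_volumes = n_volumes,
      effects = list(effect_spec(10L, 0.40, 0),
                     effect_spec(11L, baseline_r, age_slope)),
      rng_seed = derive_seed(rng_seed, "power-cohort", i))
    cohort <- simulate_cohort(cfg)
    stack <- cohort_fc_stack(cohort)
    cs <- permutation_cluster_fwe(
      stack, build_group_design(cohort$phenotypes),
      contrast_pair("pos_age_decrease"), n_perm = n_perm,
      cluster_alpha = cluster_alpha,
      rng_seed = derive_seed(rng_seed, "power-perm", i))
    target <- which(cohort$atlas$labels == 11L)
    any(vapply(which(cs$significant), function(k)
      any(which(cs$labels == k) %in% target), logical(1L)))
  }, logical(1L))
  list(detected = detected, power = mean(detected),
       n_replicates = n_replicates)
}
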