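#' Planted seed-coupling effect
#'
#' Describes one synthetic region whose BOLD signal is coupled to the
#' seed latent with a correlation that varies linearly with age:
#' rho(age) = baseline_r + age_slope_per_year * (age - cohort mean age).
#' Negative rho plants an anticorrelated region.
#'
#' @param region_label integer atlas label of the region.
#' @param baseline_r target seed coupling at the cohort mean age, in
#'   (-1, 1).
#' @param age_slope_per_year change in coupling per year of age.
#' @param side which seed latent the region couples to.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(region_label, baseline_r, age_slope_per_year = 0,
                        side = c("both", "left_seed", "right_seed")) {
  side <- match.arg(side)
  stopifnot(abs(baseline_r) < 1)
  structure(list(region_label = as.integer(region_label),
                 baseline_r = baseline_r,
                 age_slope_per_year = age_slope_per_year, side = side),
            class = "effect_spec")
}

#' Default planted effects
#'
#' Four regions whose coupling magnitudes mirror the kinds of age effects
#' the analysis is built to detect: a strong age-stable positive coupling,
#' a positive coupling declining with age (0.13 at the mean age, -0.002
#' per year), a weak positive coupling increasing with age, and an
#' anticorrelated region whose anticorrelation strengthens with age.
#'
#' @return list of [effect_spec()] objects (labels 10-13).
#' @export
default_effects <- function() {
  list(effect_spec(10L, baseline_r = 0.40, age_slope_per_year = 0),
       effect_spec(11L, baseline_r = 0.13, age_slope_per_year = -0.002),
       effect_spec(12L, baseline_r = 0.08, age_slope_per_year = +0.002),
       effect_spec(13L, baseline_r = -0.08, age_slope_per_year = -0.002))
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the multi-site aging cohort the pipeline is designed
#' for: 361 adults, ~34.5% female, ages 18-85 from 3 sites, TR 2.2 s,
#' 250 volumes, 3 mm isotropic voxels (on a compact 16^3 grid).
#'
#' @param n_subjects number of subjects (default 361).
#' @param age_range_years uniform age range (default c(18, 85)).
#' @param fraction_female Bernoulli probability of female sex (default
#'   0.345).
#' @param n_sites number of contributing sites (default 3).
#' @param grid a [volume_grid()]; default 16^3, 3 mm, TR 2.2 s.
#' @param n_volumes BOLD series length before volume discard (default
#'   250).
#' @param effects list of [effect_spec()]; default [default_effects()].
#' @param noise_sd per-voxel white-noise SD relative to the unit-variance
#'   latents (default 1).
#' @param motion_sd per-step SD of the random-walk motion traces, mm or
#'   rad (default 0.05).
#' @param motion_coupling_sd SD of the random per-voxel weights mixing
#'   the motion traces into the BOLD signal (default 0.5).
#' @param tissue_signal_sd amplitude of the global WM/CSF contamination
#'   added to every voxel (default 0.5).
#' @param drift_amplitude peak-to-peak amplitude of the linear scanner
#'   drift (default 1).
#' @param site_offset_sd SD of the site-specific mean offset (default 5).
#' @param lr_baseline_r interhemispheric seed-latent correlation at the
#'   mean age (default 0.43).
#' @param lr_age_slope change of interhemispheric coupling per year
#'   (default +0.0019).
#' @param rng_seed integer root seed; all randomness derives from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 361L,
                              age_range_years = c(18, 85),
                              fraction_female = 0.345,
                              n_sites = 3L,
                              grid = volume_grid(c(16L, 16L, 16L), 3,
                                                 tr_seconds = 2.2),
                              n_volumes = 250L,
                              effects = default_effects(),
                              noise_sd = 1,
                              motion_sd = 0.05,
                              motion_coupling_sd = 0.5,
                              tissue_signal_sd = 0.5,
                              drift_amplitude = 1,
                              site_offset_sd = 5,
                              lr_baseline_r = 0.43,
                              lr_age_slope = 0.0019,
                              rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_sites <- as.integer(n_sites)
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (n_subjects < 2L * n_sites)
    stop("need at least 2 subjects per site")
  if (n_volumes <= 24L)
    stop("n_volumes must exceed the discard count plus 20")
  stopifnot(fraction_female >= 0, fraction_female <= 1,
            age_range_years[1L] < age_range_years[2L], noise_sd >= 0)
  cfg <- structure(list(n_subjects = n_subjects,
                        age_range_years = as.numeric(age_range_years),
                        fraction_female = fraction_female, n_sites = n_sites,
                        grid = grid, n_volumes = as.integer(n_volumes),
                        effects = effects, noise_sd = noise_sd,
                        motion_sd = motion_sd,
                        motion_coupling_sd = motion_coupling_sd,
                        tissue_signal_sd = tissue_signal_sd,
                        drift_amplitude = drift_amplitude,
                        site_offset_sd = site_offset_sd,
                        lr_baseline_r = lr_baseline_r,
                        lr_age_slope = lr_age_slope,
                        rng_seed = as.integer(rng_seed)),
                   class = "simulation_config")
  mean_age <- mean(cfg$age_range_years)
  for (ef in effects) {
    rho <- ef$baseline_r +
      ef$age_slope_per_year * (cfg$age_range_years - mean_age)
    if (any(abs(rho) >= 1))
      stop("effect on label ", ef$region_label,
           " reaches |rho| >= 1 inside the age range")
  }
  cfg
}

## deterministic 31-bit stream seed from a root seed and string labels
derive_seed <- function(root, ...) {
  h <- as.double(root) %% 2147483647
  for (part in as.character(list(...))) {
    for (c in utf8ToInt(part)) h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

#' Sample cohort phenotypes
#'
#' Ages uniform over the configured range, sex Bernoulli(fraction_female),
#' sites assigned round-robin; deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a `phenotype_table` with `n_subjects` rows.
#' @export
sample_phenotypes <- function(config) {
  n <- config$n_subjects
  if (n < 2L) stop("need at least 2 subjects")
  withr::with_seed(derive_seed(config$rng_seed, "phenotypes"), {
    ids <- sprintf("sub%04d", seq_len(n))
    age <- round(stats::runif(n, config$age_range_years[1L],
                              config$age_range_years[2L]), 2L)
    sex <- ifelse(stats::runif(n) < config$fraction_female, "F", "M")
    site <- paste0("site", ((seq_len(n) - 1L) %% config$n_sites) + 1L)
    phenotype_table(data.frame(subject_id = ids, age_years = age,
                               sex = sex, site = site,
                               stringsAsFactors = FALSE))
  })
}

## place a w^3 cuboid with its lowest corner at `corner` (1-based)
place_block <- function(labels, shape, corner, w, value) {
  if (any(corner < 1L) || any(corner + w - 1L > shape))
    stop("region does not fit inside the grid")
  ix <- corner[1L]:(corner[1L] + w[1L] - 1L)
  iy <- corner[2L]:(corner[2L] + w[2L] - 1L)
  iz <- corner[3L]:(corner[3L] + w[3L] - 1L)
  vox <- as.vector(outer(outer(ix, (iy - 1L) * shape[1L], `+`),
                         (iz - 1L) * shape[1L] * shape[2L], `+`))
  if (any(labels[vox] != 0L)) stop("regions cannot be placed disjointly")
  labels[vox] <- value
  labels
}

#' Build the synthetic atlas
#'
#' Disjoint cuboid regions on the configured grid: 2x2x2 left and right
#' seed ROIs flanking the volume centre, 3^3 WM and CSF compartments in
#' opposite corners, one 3^3 block per planted effect region; every
#' remaining voxel is gray-matter background. Cuboids (rather than
#' anatomical shapes) give exact voxel counts for cluster tests.
#'
#' @param config a [simulation_config()].
#' @return a [label_volume()] (1 = gm, 2 = wm, 3 = csf, 4/5 = left/right
#'   seed, effect labels as configured).
#' @export
build_atlas <- function(config) {
  sh <- config$grid$shape
  if (any(sh < 12L)) stop("grid too small to place the atlas regions")
  labels <- integer(prod(sh))
  mid <- sh %/% 2L
  labels <- place_block(labels, sh, c(mid[1L] - 3L, mid[2L], mid[3L]), c(2L, 2L, 2L), 4L)
  labels <- place_block(labels, sh, c(mid[1L] + 2L, mid[2L], mid[3L]), c(2L, 2L, 2L), 5L)
  labels <- place_block(labels, sh, c(1L, 1L, 1L), c(3L, 3L, 3L), 2L)
  labels <- place_block(labels, sh, sh - 2L, c(3L, 3L, 3L), 3L)
  # effect blocks on a coarse lattice away from seeds and corners
  slots <- as.matrix(expand.grid(x = c(2L, 7L, 12L), y = c(2L, 7L, 12L),
                                 z = c(5L, 11L)))
  slots <- slots[order(slots[, 3L], slots[, 2L], slots[, 1L]), , drop = FALSE]
  effects <- config$effects
  if (length(effects) > nrow(slots)) stop("too many effect regions for the grid")
  si <- 0L
  for (ef in effects) {
    placed <- FALSE
    while (!placed) {
      si <- si + 1L
      if (si > nrow(slots)) stop("regions cannot be placed disjointly")
      corner <- slots[si, ]
      placed <- tryCatch({
        labels <- place_block(labels, sh, corner, c(3L, 3L, 3L), ef$region_label)
        TRUE
      }, error = function(e) FALSE)
    }
  }
  labels[labels == 0L] <- 1L
  legend <- data.frame(
    label = c(1L, 2L, 3L, 4L, 5L,
              vapply(effects, `[[`, integer(1L), "region_label")),
    role = c("gm", "wm", "csf", "seed_left", "seed_right",
             rep("effect", length(effects))),
    stringsAsFactors = FALSE)
  label_volume(labels, config$grid, legend)
}

## white noise band-passed to the analysis band, rescaled to unit SD
band_limited_series <- function(Tt, tr, band = c(0.01, 0.08), n = 1L) {
  x <- matrix(stats::rnorm(Tt * n), Tt, n)
  x <- bandpass_matrix(x, tr, band)
  sweep(x, 2L, apply(x, 2L, stats::sd), `/`)
}

## realized coupling of one effect for one subject
effect_rho <- function(effect, age, mean_age) {
  effect$baseline_r + effect$age_slope_per_year * (age - mean_age)
}

#' Simulate one subject's BOLD series and motion table
#'
#' Signal model (all latents band-limited to 0.01-0.08 Hz, unit SD):
#' left/right seed voxels carry hemispheric latents sharing an
#' age-dependent interhemispheric correlation; each effect region's
#' voxels carry `rho * s + sqrt(1 - rho^2) * eps_region` with rho from
#' its [effect_spec()] at this subject's age; every voxel additionally
#' receives i.i.d. Gaussian noise, a site-specific mean offset, a linear
#' drift, a motion-coupled component (linear mixture of the six simulated
#' motion traces), and global WM/CSF contamination. Deterministic given
#' the config seed and the subject id.
#'
#' @param row one-row phenotype entry (list or data.frame row) with
#'   `subject_id`, `age_years`, `site`.
#' @param atlas the cohort [label_volume()] from [build_atlas()].
#' @param config a [simulation_config()].
#' @param mean_age cohort mean age at which `baseline_r` applies;
#'   defaults to the midpoint of the configured age range.
#' @return list: `bold` ([bold4d()]), `motion` (`motion_table`), `rho`
#'   (named vector of this subject's realized couplings, including
#'   `lr` for the interhemispheric one).
#' @export
simulate_subject <- function(row, atlas, config,
                             mean_age = mean(config$age_range_years)) {
  Tt <- config$n_volumes
  tr <- config$grid$tr_seconds
  V <- n_voxels(config$grid)
  age <- as.numeric(row$age_years)
  rho_lr <- config$lr_baseline_r + config$lr_age_slope * (age - mean_age)
  if (abs(rho_lr) >= 1) stop("interhemispheric coupling reaches |rho| >= 1")
  rhos <- vapply(config$effects, effect_rho, numeric(1L),
                 age = age, mean_age = mean_age)
  names(rhos) <- vapply(config$effects, function(e)
    as.character(e$region_label), "")
  bad <- which(abs(rhos) >= 1)
  if (length(bad))
    stop("effect on label ", names(rhos)[bad[1L]],
         " has |rho| >= 1 at age ", age)

  withr::with_seed(derive_seed(config$rng_seed, "subject", row$subject_id), {
    # hemispheric seed latents with correlation rho_lr
    g <- band_limited_series(Tt, tr, n = 3L)
    sL <- sqrt(abs(rho_lr)) * g[, 1L] + sqrt(1 - abs(rho_lr)) * g[, 2L]
    sR <- sign(rho_lr) * sqrt(abs(rho_lr)) * g[, 1L] +
      sqrt(1 - abs(rho_lr)) * g[, 3L]
    sL <- sL / stats::sd(sL); sR <- sR / stats::sd(sR)
    sBoth <- sL + sR; sBoth <- sBoth / stats::sd(sBoth)
    side_latent <- list(both = sBoth, left_seed = sL, right_seed = sR)

    X <- matrix(stats::rnorm(Tt * V, sd = config$noise_sd), Tt, V)
    X[, label_voxels(atlas, "seed_left")] <-
      X[, label_voxels(atlas, "seed_left"), drop = FALSE] + sL
    X[, label_voxels(atlas, "seed_right")] <-
      X[, label_voxels(atlas, "seed_right"), drop = FALSE] + sR
    for (i in seq_along(config$effects)) {
      ef <- config$effects[[i]]
      vox <- which(atlas$labels == ef$region_label)
      eps <- band_limited_series(Tt, tr, n = 1L)[, 1L]
      sig <- rhos[i] * side_latent[[ef$side]] + sqrt(1 - rhos[i]^2) * eps
      X[, vox] <- X[, vox, drop = FALSE] + sig
    }
    # shared tissue signals, contaminating their compartment and (scaled)
    # every voxel, so the tissue-mean regressors have something to remove
    wm_sig <- band_limited_series(Tt, tr, n = 1L)[, 1L]
    csf_sig <- band_limited_series(Tt, tr, n = 1L)[, 1L]
    X[, label_voxels(atlas, "wm")] <- X[, label_voxels(atlas, "wm"), drop = FALSE] + wm_sig
    X[, label_voxels(atlas, "csf")] <- X[, label_voxels(atlas, "csf"), drop = FALSE] + csf_sig
    X <- X + config$tissue_signal_sd * (wm_sig + csf_sig)
    # site offset, linear drift, motion contamination
    site_i <- match(as.character(row$site), paste0("site", seq_len(config$n_sites)))
    if (is.na(site_i)) site_i <- 1L
    site_offset <- config$site_offset_sd *
      stats::qnorm((site_i) / (config$n_sites + 1L))
    drift <- config$drift_amplitude * seq(-0.5, 0.5, length.out = Tt)
    X <- X + site_offset + drift
    motion <- motion_table(apply(matrix(stats::rnorm(Tt * 6L,
                                                     sd = config$motion_sd),
                                        Tt, 6L), 2L, cumsum))
    if (config$motion_coupling_sd > 0) {
      W <- matrix(stats::rnorm(6L * V, sd = config$motion_coupling_sd), 6L, V)
      mz <- scale(unclass(motion))
      X <- X + mz %*% W
    }
    list(bold = bold4d(X, config$grid, row$subject_id), motion = motion,
         rho = c(rhos, lr = rho_lr))
  })
}

#' Simulate a full synthetic cohort
#'
#' Samples phenotypes, builds the shared atlas, simulates every subject,
#' and (optionally) writes the whole cohort to disk in the package's
#' on-disk formats: one BOLD NIfTI and one motion file per subject, the
#' atlas and its legend, a phenotype TSV with file paths, and a
#' ground-truth TSV of the realized couplings.
#'
#' @param config a [simulation_config()].
#' @param dir output directory; `NULL` (default) keeps the cohort in
#'   memory only.
#' @return list of class `synthetic_cohort`: `phenotypes`, `atlas`,
#'   `subjects` (per-subject list of `bold` + `motion`), `ground_truth`
#'   (data.frame subject x coupling), `mean_age`, `config`, `dir`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  phen <- sample_phenotypes(config)
  atlas <- build_atlas(config)
  mean_age <- mean(phen$age_years)
  subjects <- lapply(seq_len(nrow(phen)), function(i)
    simulate_subject(phen[i, ], atlas, config, mean_age = mean_age))
  names(subjects) <- phen$subject_id
  gt <- do.call(rbind, lapply(subjects, function(s) as.data.frame(t(s$rho))))
  names(gt) <- paste0("rho_", names(subjects[[1L]]$rho))
  gt <- cbind(data.frame(subject_id = phen$subject_id,
                         stringsAsFactors = FALSE), gt)
  rownames(gt) <- NULL
  cohort <- structure(list(phenotypes = phen, atlas = atlas,
                           subjects = subjects, ground_truth = gt,
                           mean_age = mean_age, config = config, dir = dir),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort to disk
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phen <- as.data.frame(cohort$phenotypes)
  phen$bold_path <- file.path("bold", paste0(phen$subject_id, "_bold.nii.gz"))
  phen$motion_path <- file.path("motion", paste0(phen$subject_id, "_motion.txt"))
  dir.create(file.path(dir, "bold"), showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (i in seq_len(nrow(phen))) {
    s <- cohort$subjects[[phen$subject_id[i]]]
    write_bold(s$bold, file.path(dir, phen$bold_path[i]))
    write_motion(s$motion, file.path(dir, phen$motion_path[i]))
  }
  write_label_volume(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  write_phenotypes(phen, file.path(dir, "phenotypes.tsv"))
  write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
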