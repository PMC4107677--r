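# small in-code fixtures shared across test files

tiny_grid <- function(shape = c(8L, 8L, 8L), vox = 3, tr = 2.2) {
  volume_grid(shape, vox, tr_seconds = tr)
}

# minimal atlas on an 8^3 grid: seeds, wm, csf, one effect block, gm rest
tiny_atlas <- function(grid = tiny_grid()) {
  labels <- integer(prod(grid$shape))
  idx <- function(x, y, z) {
    g <- as.matrix(expand.grid(x = x, y = y, z = z))
    g[, 1] + grid$shape[1] * (g[, 2] - 1 + grid$shape[2] * (g[, 3] - 1))
  }
  labels[idx(2:3, 4:5, 4:5)] <- 4L   # seed_left
  labels[idx(6:7, 4:5, 4:5)] <- 5L   # seed_right
  labels[idx(1:2, 1:2, 1:2)] <- 2L   # wm
  labels[idx(7:8, 7:8, 7:8)] <- 3L   # csf
  labels[idx(4:6, 1:3, 6:8)] <- 10L  # effect block
  labels[labels == 0L] <- 1L
  label_volume(labels, grid, data.frame(
    label = c(1L, 2L, 3L, 4L, 5L, 10L),
    role = c("gm", "wm", "csf", "seed_left", "seed_right", "effect")))
}

rand_bold <- function(grid = tiny_grid(), Tt = 40L, sd = 1, seed = 1,
                      subject_id = "s1") {
  withr::with_seed(seed, {
    bold4d(matrix(rnorm(Tt * prod(grid$shape), sd = sd), Tt), grid, subject_id)
  })
}

tiny_phenotypes <- function(n = 12L, seed = 1L) {
  withr::with_seed(seed, {
    phenotype_table(data.frame(
      subject_id = sprintf("s%02d", seq_len(n)),
      age_years = seq(20, 80, length.out = n),
      sex = rep_len(c("F", "M"), n),
      site = rep_len(paste0("site", 1:3), n)))
  })
}

# small simulated cohort used by several test files
small_config <- function(n_subjects = 12L, n_volumes = 60L, seed = 11L, ...) {
  simulation_config(n_subjects = n_subjects, n_volumes = n_volumes,
                    rng_seed = seed, ...)
}

# null-coupling variant: planted baselines but no age slopes
null_effects <- function() {
  list(effect_spec(10L, 0.40, 0), effect_spec(11L, 0.13, 0),
       effect_spec(12L, 0.08, 0), effect_spec(13L, -0.08, 0))
}

# preprocess + bilateral z-maps for every subject of a cohort
cohort_zmaps <- function(cohort, source = "bilateral",
                         config = preproc_config()) {
  lapply(cohort$subjects, function(s) {
    b <- preprocess_subject(s$bold, s$motion, cohort$atlas, config)
    fc_zmap(b, seed_series(b, cohort$atlas, source),
            analysis_mask(cohort$atlas))
  })
}
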