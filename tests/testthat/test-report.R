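test_that("split-half sizes follow the floor(N/2) rule with median exclusion", {
  cfg <- simulation_config(n_subjects = 361L, rng_seed = 3L)
  ph <- sample_phenotypes(cfg)
  sp <- split_half(ph)
  expect_length(sp$young_ids, 180L)
  expect_length(sp$old_ids, 180L)
  expect_length(sp$excluded_id, 1L)
  ages <- ph$age_years[match(c(sp$young_ids, sp$old_ids), ph$subject_id)]
  expect_lte(max(ages[1:180]), min(ages[181:360]))

  even <- split_half(tiny_phenotypes(10L))
  expect_length(even$young_ids, 5L); expect_length(even$old_ids, 5L)
  expect_null(even$excluded_id)

  odd <- split_half(tiny_phenotypes(7L))
  expect_length(odd$young_ids, 3L); expect_length(odd$old_ids, 3L)
  # the excluded subject is the age median
  ph7 <- tiny_phenotypes(7L)
  expect_identical(odd$excluded_id,
                   ph7$subject_id[order(ph7$age_years, ph7$subject_id)][4L])
  expect_error(split_half(tiny_phenotypes(3L)), "at least 4")
  # deterministic across repeated calls
  expect_identical(split_half(ph), sp)
})

test_that("cluster subject coupling is tanh of the mean Fisher-Z", {
  ph <- tiny_phenotypes(8L)
  grid <- tiny_grid(c(3L, 3L, 3L))
  Z <- withr::with_seed(20, matrix(rnorm(8 * 27, sd = 0.3), 8))
  stack <- list(Z = Z, mask = rep(TRUE, 27L), grid = grid,
                subject_ids = ph$subject_id)
  # single-voxel cluster: r equals that voxel's own r exactly
  fc1 <- cluster_subject_fc(13L, stack)
  expect_equal(fc1$r, tanh(Z[, 13L]), ignore_attr = TRUE, tolerance = 1e-12)
  # all voxels share one z: r = tanh(z)
  stack$Z[, 1:5] <- stack$Z[, 1L]
  fc2 <- cluster_subject_fc(1:5, stack)
  expect_equal(fc2$r, tanh(stack$Z[, 1L]), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(cluster_subject_fc(integer(0), stack), "empty")
})

test_that("cluster statistics match textbook Welch and Spearman oracles", {
  ph <- tiny_phenotypes(12L)
  grid <- tiny_grid(c(3L, 3L, 3L))
  Z <- withr::with_seed(21, matrix(rnorm(12 * 27, sd = 0.2), 12))
  stack <- list(Z = Z, mask = rep(TRUE, 27L), grid = grid,
                subject_ids = ph$subject_id)
  sp <- split_half(ph)
  st <- cluster_stats(1:4, stack, ph, sp)
  z <- rowMeans(Z[, 1:4]); names(z) <- ph$subject_id
  zy <- z[sp$young_ids]; zo <- z[sp$old_ids]
  # explicit Welch formula
  want_t <- (mean(zy) - mean(zo)) /
    sqrt(var(zy) / length(zy) + var(zo) / length(zo))
  expect_equal(st$t_delta_r, want_t, tolerance = 1e-10)
  expect_equal(st$mean_r_young, mean(tanh(zy)), tolerance = 1e-12)
  expect_equal(st$spearman_age,
               cor(rank(z), rank(ph$age_years)), tolerance = 1e-10)

  # strictly monotone z vs age -> Spearman exactly 1
  Zm <- matrix(rep(sort(ph$age_years) / 100, 27), 12)
  stack2 <- list(Z = Zm[order(order(ph$age_years)), , drop = FALSE],
                 mask = rep(TRUE, 27L), grid = grid,
                 subject_ids = ph$subject_id)
  st2 <- cluster_stats(5L, stack2, ph, sp)
  expect_equal(st2$spearman_age, 1, tolerance = 1e-12)
  # declining coupling gives positive t (young > old)
  expect_gt(st2$t_delta_r * -1, 0)
})

test_that("the effect filter keeps |r| > 0.1 in either half and is sign-symmetric", {
  mk <- function(y, o) list(mean_r_young = y, mean_r_old = o)
  expect_true(effect_filter(mk(0.15, 0.0)))
  expect_false(effect_filter(mk(0.05, -0.05)))
  expect_true(effect_filter(mk(0.0, -0.12)))
  expect_false(effect_filter(mk(0.1, 0.1)))  # strict inequality
  # symmetric under global sign flip
  for (case in list(c(0.15, 0), c(0.05, -0.05), c(0, -0.12)))
    expect_identical(effect_filter(mk(case[1], case[2])),
                     effect_filter(mk(-case[1], -case[2])))
})

test_that("finalized cluster tables carry world-mm peaks and filtered rows", {
  cfg <- small_config(n_subjects = 16L, n_volumes = 60L, seed = 31L)
  co <- simulate_cohort(cfg)
  st <- stack_fc_maps(cohort_zmaps(co))
  des <- build_group_design(co$phenotypes)
  age_c <- co$phenotypes$age_years - mean(co$phenotypes$age_years)
  blk <- which(co$atlas$labels == 10L)
  st$Z[, blk] <- st$Z[, blk] + 1 - age_c %o% rep(0.06, length(blk))
  cs <- permutation_cluster_fwe(st, des, contrast_pair("pos_age_decrease"),
                                n_perm = 120L, rng_seed = 9L)
  fin <- finalize_clusters(cs, st, co$phenotypes)
  tab <- cluster_table(fin)
  expect_gte(nrow(tab), 1L)
  # peak world coordinates equal affine * 0-based index
  k <- tab$cluster_id[1L]
  pk <- cs$peaks[cs$peaks$cluster_id == k, ]
  mm <- voxel_to_world(co$atlas$grid, cbind(pk$i0, pk$j0, pk$k0))
  expect_equal(unlist(tab[1L, c("peak_x_mm", "peak_y_mm", "peak_z_mm")]),
               mm[1, ], ignore_attr = TRUE, tolerance = 1e-10)
  # all rows pass the effect filter
  expect_true(all(abs(tab$mean_r_young) > 0.1 | abs(tab$mean_r_old) > 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(fin, path)
  back <- read_cluster_table(path)
  expect_equal(back$p_fwe, tab$p_fwe, tolerance = 1e-6)
})

test_that("hemispheric difference analysis is antisymmetric and null for shared seeds", {
  cfg <- small_config(n_subjects = 12L, n_volumes = 60L, seed = 37L)
  co <- simulate_cohort(cfg)
  zl <- cohort_zmaps(co, "left")
  zr <- cohort_zmaps(co, "right")
  sl <- stack_fc_maps(zl); sr <- stack_fc_maps(zr)
  des <- build_group_design(co$phenotypes)
  # identical stacks -> D == 0, no clusters anywhere
  res0 <- hemispheric_analysis(sl, sl, des,
                               pairs = list(contrast_pair("pos_age_decrease")),
                               n_perm = 100L, rng_seed = 3L)
  expect_identical(res0$pos_age_decrease$n_clusters, 0L)
  # swapping left/right negates the D t-map exactly
  r1 <- hemispheric_analysis(sl, sr, des,
                             pairs = list(contrast_pair("pos_age_decrease")),
                             n_perm = 100L, rng_seed = 3L)
  r2 <- hemispheric_analysis(sr, sl, des,
                             pairs = list(contrast_pair("pos_age_decrease")),
                             n_perm = 100L, rng_seed = 3L)
  expect_equal(r1$pos_age_decrease$maps$t_main,
               -r2$pos_age_decrease$maps$t_main, tolerance = 1e-8)
  sr2 <- sr; sr2$subject_ids <- rev(sr$subject_ids)
  expect_error(hemispheric_analysis(sl, sr2, des, n_perm = 100L, rng_seed = 1L),
               "different subjects")
})

test_that("a left-lateralized planted coupling appears in the hemispheric contrast", {
  cfg <- simulation_config(
    n_subjects = 30L, n_volumes = 120L, rng_seed = 41L,
    effects = list(effect_spec(10L, 0.6, 0, side = "left_seed")))
  co <- simulate_cohort(cfg)
  sl <- stack_fc_maps(cohort_zmaps(co, "left"))
  sr <- stack_fc_maps(cohort_zmaps(co, "right"))
  des <- build_group_design(co$phenotypes)
  dstack <- list(Z = sl$Z - sr$Z, mask = sl$mask & sr$mask, grid = sl$grid,
                 subject_ids = sl$subject_ids)
  maps <- fit_glm_tmaps(dstack, des)
  target <- which(co$atlas$labels == 10L)
  t_crit <- qt(1 - 0.001, maps$df)
  expect_gt(median(maps$t_main[target]), t_crit)
})

test_that("interhemispheric coupling statistics track the planted age trend", {
  cfg <- simulation_config(n_subjects = 40L, n_volumes = 120L, rng_seed = 43L,
                           lr_baseline_r = 0.43, lr_age_slope = 0.0019,
                           effects = list(effect_spec(10L, 0.3, 0)))
  co <- simulate_cohort(cfg)
  pp <- lapply(co$subjects, function(s)
    preprocess_subject(s$bold, s$motion, co$atlas, preproc_config()))
  res <- interhemispheric_fc_vs_age(pp, co$atlas, co$phenotypes)
  # coupling is strong and increases from the young to the old half
  expect_gt(res$mean_r_young, 0.2)
  expect_gt(res$mean_r_old, res$mean_r_young)
  expect_gt(res$spearman_age, 0)
  # noise-free shared latent -> per-subject r near 1
  cfg1 <- simulation_config(n_subjects = 4L, n_volumes = 60L, rng_seed = 44L, n_sites = 1L,
                            lr_baseline_r = 1 - 1e-9, lr_age_slope = 0,
                            noise_sd = 0, motion_coupling_sd = 0,
                            tissue_signal_sd = 0, drift_amplitude = 0,
                            site_offset_sd = 0,
                            effects = list(effect_spec(10L, 0.3, 0)))
  co1 <- simulate_cohort(cfg1)
  b <- co1$subjects[[1]]$bold
  l <- seed_series(b, co1$atlas, "left"); r <- seed_series(b, co1$atlas, "right")
  expect_gt(abs(cor(l$values, r$values)), 0.999)
})
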