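test_that("group design has intercept, centered age, sex, and effect-coded sites", {
  ph <- tiny_phenotypes(30L)
  des <- build_group_design(ph)
  expect_identical(des$column_names, c("intercept", "age", "sex", "site1", "site2"))
  expect_identical(des$df_residual, 25L)
  expect_lt(abs(sum(des$matrix[, 2])), 1e-10)
  expect_lt(max(abs(colMeans(des$matrix[, -1]))), 1e-10)
  # N=361 with 3 sites: 361 x 5, df 356
  cfg <- simulation_config(n_subjects = 361L, rng_seed = 2L)
  des361 <- build_group_design(sample_phenotypes(cfg))
  expect_identical(dim(des361$matrix), c(361L, 5L))
  expect_identical(des361$df_residual, 356L)
})

test_that("degenerate covariates are dropped and collinearity is refused", {
  ph <- tiny_phenotypes(12L)
  ph$sex <- factor(rep("M", 12L))
  ph$site <- factor(rep("A", 12L))
  expect_warning(expect_warning(des <- build_group_design(ph), "sex"), "site")
  expect_identical(ncol(des$matrix), 2L)
  ph2 <- tiny_phenotypes(12L)
  ph2$age_years <- rep(40, 12L)   # zero-variance age -> collinear with intercept
  expect_error(suppressWarnings(build_group_design(ph2)), "collinear|singular")
})

test_that("GLM t-maps match a normal-equations oracle to 1e-8", {
  ph <- tiny_phenotypes(40L, seed = 3L)
  des <- build_group_design(ph)
  grid <- tiny_grid(c(4L, 4L, 4L))
  V <- prod(grid$shape)
  Z <- withr::with_seed(14, matrix(rnorm(40 * V), 40))
  stack <- list(Z = Z, mask = rep(TRUE, V), grid = grid,
                subject_ids = ph$subject_id)
  maps <- fit_glm_tmaps(stack, des)
  # brute-force (X'X)^-1 X'y per voxel
  X <- des$matrix
  XtXinv <- solve(t(X) %*% X)
  for (v in c(1L, 17L, V)) {
    beta <- XtXinv %*% t(X) %*% Z[, v]
    resid <- Z[, v] - X %*% beta
    s2 <- sum(resid^2) / des$df_residual
    t_int <- beta[1] / sqrt(s2 * XtXinv[1, 1])
    t_age <- beta[2] / sqrt(s2 * XtXinv[2, 2])
    expect_equal(maps$t_main[v], t_int, tolerance = 1e-8)
    expect_equal(maps$t_age[v], t_age, tolerance = 1e-8)
    expect_equal(maps$beta_age[v], beta[2], tolerance = 1e-10)
  }
})

test_that("noise-free linear maps are recovered exactly with capped t", {
  ph <- tiny_phenotypes(20L, seed = 4L)
  des <- build_group_design(ph)
  grid <- tiny_grid(c(2L, 2L, 2L))
  age_c <- ph$age_years - mean(ph$age_years)
  Z <- outer(rep(1, 20), rep(0.3, 8)) + age_c %o% rep(0.002, 8)
  stack <- list(Z = Z, mask = rep(TRUE, 8L), grid = grid,
                subject_ids = ph$subject_id)
  maps <- fit_glm_tmaps(stack, des)
  expect_equal(maps$beta_main, rep(0.3, 8), tolerance = 1e-10)
  expect_equal(maps$beta_age, rep(0.002, 8), tolerance = 1e-10)
  expect_true(all(abs(maps$t_age) == 1e6))
})

test_that("subject reordering leaves the fitted maps unchanged", {
  ph <- tiny_phenotypes(16L, seed = 5L)
  grid <- tiny_grid(c(3L, 3L, 3L))
  V <- prod(grid$shape)
  Z <- withr::with_seed(15, matrix(rnorm(16 * V), 16))
  stack <- list(Z = Z, mask = rep(TRUE, V), grid = grid,
                subject_ids = ph$subject_id)
  maps <- fit_glm_tmaps(stack, build_group_design(ph))
  perm <- withr::with_seed(16, sample(16L))
  stack2 <- stack; stack2$Z <- Z[perm, ]; stack2$subject_ids <- ph$subject_id[perm]
  maps2 <- fit_glm_tmaps(stack2, build_group_design(ph[perm, ]))
  expect_equal(maps2$t_main, maps$t_main, tolerance = 1e-10)
  expect_equal(maps2$t_age, maps$t_age, tolerance = 1e-10)
})

test_that("cluster labeling agrees with a brute-force BFS oracle at all connectivities", {
  # independent pure-R flood fill
  bfs_label <- function(pass, dims, conn) {
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    nz <- rowSums(abs(offs))
    offs <- offs[nz > 0 & nz <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(conn)], ,
                 drop = FALSE]
    lab <- integer(length(pass)); nxt <- 0L
    coord <- cbind((seq_along(pass) - 1L) %% dims[1],
                   ((seq_along(pass) - 1L) %/% dims[1]) %% dims[2],
                   (seq_along(pass) - 1L) %/% (dims[1] * dims[2]))
    for (v in seq_along(pass)) {
      if (!pass[v] || lab[v]) next
      nxt <- nxt + 1L; queue <- v; lab[v] <- nxt
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        nb <- sweep(offs, 2, coord[cur, ], `+`)
        ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] & nb[, 2] >= 0 &
          nb[, 2] < dims[2] & nb[, 3] >= 0 & nb[, 3] < dims[3]
        ids <- nb[ok, 1] + dims[1] * (nb[ok, 2] + dims[2] * nb[ok, 3]) + 1L
        new <- ids[pass[ids] & lab[ids] == 0L]
        lab[new] <- nxt; queue <- c(queue, new)
      }
    }
    lab
  }
  dims <- c(8L, 8L, 8L)
  for (seed in 1:4) {
    pass <- withr::with_seed(seed, runif(prod(dims)) < 0.2)
    for (conn in c(6L, 18L, 26L)) {
      got <- label_components(pass, dims, conn)
      want <- bfs_label(pass, dims, conn)
      # same partition (labels may be permuted): compare canonical forms
      expect_identical(got$labels > 0L, want > 0L)
      expect_identical(sort(as.integer(table(want[want > 0L]))),
                       sort(got$sizes))
      # voxel pairs share a cluster in one labeling iff they do in the other
      on <- which(pass)
      expect_identical(outer(got$labels[on], got$labels[on], `==`),
                       outer(want[on], want[on], `==`))
    }
  }
})

test_that("connectivity is monotone: 6-clusters refine 26-clusters", {
  dims <- c(8L, 8L, 8L)
  pass <- withr::with_seed(9, runif(prod(dims)) < 0.25)
  l6 <- label_components(pass, dims, 6L)$labels
  l26 <- label_components(pass, dims, 26L)$labels
  for (k in seq_len(max(l6)))
    expect_length(unique(l26[l6 == k]), 1L)
})

test_that("conjunction clusters require both one-sided tests to pass", {
  ph <- tiny_phenotypes(20L, seed = 6L)
  des <- build_group_design(ph)
  grid <- tiny_grid()
  V <- prod(grid$shape)
  Z <- withr::with_seed(17, matrix(rnorm(20 * V, sd = 0.05), 20))
  age_c <- ph$age_years - mean(ph$age_years)
  # voxels 1:27 carry positive FC declining with age; voxel 100 only main effect
  blk <- 1:27
  Z[, blk] <- Z[, blk] + 0.5 - age_c %o% rep(0.01, 27)
  Z[, 100] <- Z[, 100] + 0.5
  stack <- list(Z = Z, mask = rep(TRUE, V), grid = grid,
                subject_ids = ph$subject_id)
  maps <- fit_glm_tmaps(stack, des)
  cs <- conjunction_clusters(maps, contrast_pair("pos_age_decrease"),
                             forming_p = 0.001, connectivity = 26L)
  pass_set <- which(cs$labels > 0L)
  t_crit <- qt(1 - 0.001, maps$df)
  # conjunction pass-set is a subset of each single-map pass-set
  expect_true(all(maps$t_main[pass_set] > t_crit))
  expect_true(all(maps$t_age[pass_set] < -t_crit))
  expect_false(100 %in% pass_set)
  # age map all zero -> empty set
  maps0 <- maps; maps0$t_age <- numeric(V)
  expect_identical(conjunction_clusters(maps0, contrast_pair("pos_age_decrease"))$n_clusters, 0L)
  # single passing voxel forms one cluster of size 1
  maps1 <- maps
  maps1$t_main <- numeric(V); maps1$t_age <- numeric(V)
  maps1$t_main[200] <- 10; maps1$t_age[200] <- -10
  cs1 <- conjunction_clusters(maps1, contrast_pair("pos_age_decrease"))
  expect_identical(cs1$sizes, 1L)
  expect_identical(cs1$peaks$voxel_id, 200L)
})

test_that("voxel-forming threshold matches an independent Student-t quantile", {
  # qt checked against the regularized incomplete beta relation
  df <- 356; p <- 0.001
  t_crit <- qt(1 - p, df)
  # independent check: P(T > t_crit) via pbeta tail of t distribution
  tail <- pbeta(df / (df + t_crit^2), df / 2, 0.5) / 2
  expect_equal(tail, p, tolerance = 1e-9)
  ph <- tiny_phenotypes(20L, seed = 8L)
  des <- build_group_design(ph)
  grid <- tiny_grid(c(3L, 3L, 3L))
  Z <- withr::with_seed(19, matrix(rnorm(20 * 27), 20))
  maps <- fit_glm_tmaps(list(Z = Z, mask = rep(TRUE, 27L), grid = grid,
                             subject_ids = ph$subject_id), des)
  cs <- conjunction_clusters(maps, contrast_pair("pos_age_decrease"),
                             forming_p = p)
  expect_equal(cs$t_crit, qt(1 - p, maps$df), tolerance = 1e-10)
})

test_that("permutation FWE p-values respect the add-one floor and flag thresholds", {
  cfg <- small_config(n_subjects = 16L, n_volumes = 60L, seed = 23L)
  co <- simulate_cohort(cfg)
  st <- stack_fc_maps(cohort_zmaps(co))
  des <- build_group_design(co$phenotypes)
  # strong planted decline so the observed cluster dominates every permutation
  age_c <- co$phenotypes$age_years - mean(co$phenotypes$age_years)
  blk <- which(co$atlas$labels == 10L)
  st$Z[, blk] <- st$Z[, blk] + 1 - age_c %o% rep(0.06, length(blk))
  cs <- permutation_cluster_fwe(st, des, contrast_pair("pos_age_decrease"),
                                n_perm = 199L, rng_seed = 5L)
  expect_gte(cs$n_clusters, 1L)
  big <- which.max(cs$sizes)
  expect_equal(cs$p_fwe[big], 1 / 200, tolerance = 1e-12)
  expect_true(all(cs$p_fwe >= 1 / 200 & cs$p_fwe <= 1))
  expect_true(cs$significant[big])
  # p_fwe monotone non-increasing in cluster size under the same null
  ord <- order(cs$sizes)
  expect_true(all(diff(cs$p_fwe[ord]) <= 1e-12))
  expect_error(permutation_cluster_fwe(st, des, contrast_pair("pos_age_decrease"),
                                       n_perm = 50L, rng_seed = 1L),
               "at least 100")
  expect_error(permutation_cluster_fwe(st, des, contrast_pair("pos_age_decrease"),
                                       n_perm = 199L),
               "rng_seed")
})

test_that("permutation inference is reproducible given the seed", {
  cfg <- small_config(n_subjects = 12L, n_volumes = 60L, seed = 29L)
  co <- simulate_cohort(cfg)
  st <- stack_fc_maps(cohort_zmaps(co))
  des <- build_group_design(co$phenotypes)
  cs1 <- permutation_cluster_fwe(st, des, contrast_pair("pos_age_increase"),
                                 n_perm = 120L, rng_seed = 77L)
  cs2 <- permutation_cluster_fwe(st, des, contrast_pair("pos_age_increase"),
                                 n_perm = 120L, rng_seed = 77L)
  expect_identical(cs1$null_max_sizes, cs2$null_max_sizes)
  expect_identical(cs1$p_fwe, cs2$p_fwe)
})

test_that("a strong planted age decline is detected with cluster-level FWE", {
  # power property at a comfortably detectable slope (0.004 z/yr, T=250)
  hits <- vapply(1:5, function(seed) {
    cfg <- simulation_config(
      n_subjects = 80L, n_volumes = 250L, rng_seed = seed + 400L,
      effects = list(effect_spec(10L, 0.40, 0),
                     effect_spec(11L, 0.15, -0.004)))
    co <- simulate_cohort(cfg)
    st <- stack_fc_maps(cohort_zmaps(co))
    cs <- permutation_cluster_fwe(st, build_group_design(co$phenotypes),
                                  contrast_pair("pos_age_decrease"),
                                  n_perm = 300L, rng_seed = seed)
    target <- which(co$atlas$labels == 11L)
    any(vapply(which(cs$significant), function(k)
      any(which(cs$labels == k) %in% target), logical(1L)))
  }, logical(1L))
  expect_gte(sum(hits), 4L)
})
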