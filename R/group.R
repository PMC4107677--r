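t_value_cap <- 1e6

#' Build the group-level design matrix
#'
#' Covariate-adjusted one-group model: intercept (adjusted grand mean),
#' mean-centered age in years, sex coded +/-0.5 then centered, site
#' effect-coded (sum-to-zero) with `n_sites - 1` centered columns. With
#' all covariates centered, the intercept tests the adjusted mean FC.
#' Zero-variance covariates (single-sex or single-site cohorts) are
#' dropped with a warning.
#'
#' @param phenotypes a `phenotype_table`.
#' @return list of class `group_design`: `matrix` (N x P),
#'   `column_names`, `df_residual`, `age_col`.
#' @export
build_group_design <- function(phenotypes) {
  ph <- phenotype_table(phenotypes)
  N <- nrow(ph)
  age <- ph$age_years - mean(ph$age_years)
  X <- cbind(intercept = 1, age = age)
  if (nlevels(droplevels(ph$sex)) >= 2L) {
    sex <- ifelse(ph$sex == levels(droplevels(ph$sex))[1L], -0.5, 0.5)
    X <- cbind(X, sex = sex - mean(sex))
  } else {
    warning("single-level sex covariate dropped")
  }
  site <- droplevels(ph$site)
  if (nlevels(site) >= 2L) {
    S <- stats::contr.sum(nlevels(site))[as.integer(site), , drop = FALSE]
    S <- scale(S, center = TRUE, scale = FALSE)
    colnames(S) <- paste0("site", seq_len(ncol(S)))
    X <- cbind(X, S)
  } else {
    warning("single-level site covariate dropped")
  }
  P <- ncol(X)
  if (N <= P) stop("need more subjects (", N, ") than design columns (", P, ")")
  qx <- qr(X)
  if (qx$rank < P) {
    bad <- colnames(X)[setdiff(seq_len(P), qx$pivot[seq_len(qx$rank)])]
    stop("collinear design column(s): ", paste(bad, collapse = ", "))
  }
  if (abs(mean(X[, "age"])) > 1e-10) stop("age column failed to center")
  structure(list(matrix = unname(X), column_names = colnames(X),
                 df_residual = N - P, age_col = which(colnames(X) == "age")),
            class = "group_design")
}

#' Voxel-wise group GLM t-maps
#'
#' Ordinary least squares per in-mask voxel; t = beta / SE(beta) with the
#' residual-variance SE at `df_residual` degrees of freedom. Degenerate
#' zero-residual fits are capped at |t| = 1e6. Returns t-maps for the
#' intercept (FC main effect) and age columns.
#'
#' @param stack output of [stack_fc_maps()] (or a list with `Z`, `mask`,
#'   `grid`).
#' @param design a `group_design` whose rows match the subject order of
#'   the stack.
#' @return list of class `stat_maps`: `t_main`, `t_age` (length-V
#'   vectors, 0 outside mask), `beta_main`, `beta_age`, `df`, `mask`,
#'   `grid`.
#' @export
fit_glm_tmaps <- function(stack, design) {
  X <- design$matrix
  N <- nrow(X)
  if (nrow(stack$Z) != N) stop("subject count mismatch between maps and design")
  idx <- which(stack$mask)
  Y <- stack$Z[, idx, drop = FALSE]
  XtXinv <- solve(crossprod(X))
  XtY <- crossprod(X, Y)
  B <- XtXinv %*% XtY
  rss <- colSums(Y^2) - colSums(XtY * B)
  df <- design$df_residual
  sigma2 <- pmax(rss, 0) / df
  tstat <- function(col) {
    se <- sqrt(sigma2 * XtXinv[col, col])
    t <- ifelse(se > 0, B[col, ] / se, sign(B[col, ]) * t_value_cap)
    pmin(pmax(t, -t_value_cap), t_value_cap)
  }
  tovec <- function(v) { out <- numeric(length(stack$mask)); out[idx] <- v; out }
  a <- design$age_col
  structure(list(t_main = tovec(tstat(1L)), t_age = tovec(tstat(a)),
                 beta_main = tovec(B[1L, ]), beta_age = tovec(B[a, ]),
                 df = df, mask = stack$mask, grid = stack$grid),
            class = "stat_maps")
}

#' Conjunction contrast pairs
#'
#' The four directional conjunctions of an FC main effect with an age
#' effect: e.g. `pos_age_decrease` requires positive FC (t_main above the
#' one-sided critical value) AND an age-related decrease (t_age below its
#' negative).
#'
#' @param name one of "pos_age_decrease", "pos_age_increase",
#'   "neg_age_decrease", "neg_age_increase".
#' @return list with `name`, `main_dir`, `age_dir` (+1/-1). For the
#'   "neg_*" pairs the main direction is -1 (anticorrelation);
#'   "neg_age_decrease" means weakening anticorrelation (age_dir +1).
#' @export
contrast_pair <- function(name = c("pos_age_decrease", "pos_age_increase",
                                   "neg_age_decrease", "neg_age_increase")) {
  name <- match.arg(name)
  dirs <- switch(name,
    pos_age_decrease = c(+1L, -1L),
    pos_age_increase = c(+1L, +1L),
    neg_age_decrease = c(-1L, +1L),   # anticorrelation weakens with age
    neg_age_increase = c(-1L, -1L))
  list(name = name, main_dir = dirs[1L], age_dir = dirs[2L])
}

#' Label connected components of a 3D mask
#'
#' @param pass logical vector of length V (column-major, x fastest).
#' @param grid a [volume_grid()] (or integer shape of length 3).
#' @param connectivity 6, 18 or 26 (face / face+edge / face+edge+corner
#'   neighbourhoods).
#' @return list: `labels` (integer vector, 0 = background, clusters
#'   numbered 1..K in first-voxel order), `sizes`.
#' @export
label_components <- function(pass, grid, connectivity = 26L) {
  shape <- if (inherits(grid, "volume_grid")) grid$shape else as.integer(grid)
  .label_components_cpp(as.logical(pass), as.integer(shape),
                        as.integer(connectivity))
}

#' Form conjunction clusters (uncorrected)
#'
#' A voxel passes iff both one-sided tests clear the voxel-forming
#' threshold in the directions of the contrast pair; connected components
#' of the pass set are then labeled. Peaks maximize the conjunction
#' minimum statistic min(main_dir * t_main, age_dir * t_age).
#'
#' @param maps a `stat_maps` object from [fit_glm_tmaps()].
#' @param pair a [contrast_pair()].
#' @param forming_p one-sided voxel-level p threshold (default 0.001).
#' @param connectivity 6, 18 or 26.
#' @return list of class `cluster_set`: `labels`, `sizes`, `peaks`
#'   (data.frame: cluster_id, voxel_id, index0 triple, t), `n_clusters`,
#'   `connectivity`, `forming_p`, `pair`, `grid`, plus `t_crit`.
#' @export
conjunction_clusters <- function(maps, pair, forming_p = 0.001,
                                 connectivity = 26L) {
  t_crit <- stats::qt(1 - forming_p, df = maps$df)
  conj <- pmin(pair$main_dir * maps$t_main, pair$age_dir * maps$t_age)
  pass <- maps$mask & (conj > t_crit)
  lab <- label_components(pass, maps$grid, connectivity)
  K <- length(lab$sizes)
  peaks <- data.frame(cluster_id = integer(0), voxel_id = integer(0),
                      i0 = integer(0), j0 = integer(0), k0 = integer(0),
                      t = numeric(0))
  if (K > 0L) {
    peaks <- do.call(rbind, lapply(seq_len(K), function(k) {
      vox <- which(lab$labels == k)
      pk <- vox[which.max(conj[vox])]
      idx0 <- voxel_id_to_index0(maps$grid, pk)
      data.frame(cluster_id = k, voxel_id = pk,
                 i0 = idx0[1L], j0 = idx0[2L], k0 = idx0[3L], t = conj[pk])
    }))
  }
  structure(list(labels = lab$labels, sizes = lab$sizes, peaks = peaks,
                 n_clusters = K, connectivity = as.integer(connectivity),
                 forming_p = forming_p, pair = pair, grid = maps$grid,
                 t_crit = t_crit, df = maps$df),
            class = "cluster_set")
}

#' Cluster-level FWE correction by Freedman-Lane permutation
#'
#' Builds the null distribution of the maximum conjunction-cluster size
#' by permuting the reduced-model (no-age) residuals, refitting the full
#' model, re-thresholding the age t-map, and intersecting with the FIXED
#' observed main-effect pass set. Each observed cluster gets
#' `p_fwe = (1 + #[perm max >= size]) / (1 + n_perm)`; clusters with
#' `p_fwe < cluster_alpha` are flagged significant, and a liberal flag at
#' `p_fwe < liberal_alpha` is reported separately.
#'
#' @param stack output of [stack_fc_maps()].
#' @param design a `group_design`.
#' @param pair a [contrast_pair()].
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param forming_p voxel-forming one-sided p (default 0.001).
#' @param cluster_alpha cluster-level significance (default 0.05).
#' @param liberal_alpha exploratory cluster-level threshold (default 0.1).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param rng_seed integer seed for the permutation draw (required).
#' @return a `cluster_set` with `p_fwe`, `significant`,
#'   `significant_liberal`, `null_max_sizes`, and the fitted `stat_maps`
#'   attached as `$maps`.
#' @export
permutation_cluster_fwe <- function(stack, design, pair,
                                    n_perm = 1000L, forming_p = 0.001,
                                    cluster_alpha = 0.05, liberal_alpha = 0.1,
                                    connectivity = 26L, rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) stop("rng_seed is required")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  maps <- fit_glm_tmaps(stack, design)
  cs <- conjunction_clusters(maps, pair, forming_p, connectivity)

  X <- design$matrix
  N <- nrow(X)
  idx <- which(stack$mask)
  main_pass <- (pair$main_dir * maps$t_main[idx]) > cs$t_crit
  perms <- withr::with_seed(rng_seed, {
    t(replicate(n_perm, sample.int(N))) - 1L
  })
  null_max <- .fl_max_cluster_cpp(t(stack$Z[, idx, drop = FALSE]), X,
                                  design$age_col - 1L, perms,
                                  main_pass, idx, stack$grid$shape,
                                  cs$t_crit, pair$age_dir,
                                  as.integer(connectivity), t_value_cap)
  p_fwe <- vapply(cs$sizes, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                  numeric(1L))
  cs$p_fwe <- p_fwe
  cs$significant <- p_fwe < cluster_alpha
  cs$significant_liberal <- p_fwe < liberal_alpha
  cs$cluster_alpha <- cluster_alpha
  cs$liberal_alpha <- liberal_alpha
  cs$n_perm <- n_perm
  cs$null_max_sizes <- as.integer(null_max)
  cs$maps <- maps
  cs
}
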