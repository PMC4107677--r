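#' Split the cohort into younger and older halves
#'
#' Subjects are sorted by age (ties broken by subject_id, so the split is
#' deterministic); the lower floor(N/2) form the younger group and the
#' upper floor(N/2) the older group. For odd N the median subject is
#' excluded, so a 361-subject cohort yields 180 vs 180.
#'
#' @param phenotypes a `phenotype_table` with at least 4 subjects.
#' @return list of class `split_half`: `young_ids`, `old_ids`,
#'   `excluded_id` (NULL for even N).
#' @export
split_half <- function(phenotypes) {
  ph <- phenotype_table(phenotypes)
  N <- nrow(ph)
  if (N < 4L) stop("split-half needs at least 4 subjects")
  ord <- order(ph$age_years, ph$subject_id)
  half <- N %/% 2L
  young <- ph$subject_id[ord[seq_len(half)]]
  old <- ph$subject_id[ord[seq.int(N - half + 1L, N)]]
  excluded <- if (N %% 2L == 1L) ph$subject_id[ord[half + 1L]] else NULL
  structure(list(young_ids = young, old_ids = old, excluded_id = excluded),
            class = "split_half")
}

#' Per-subject cluster coupling
#'
#' A subject's coupling with a cluster: the mean Fisher-Z over the
#' cluster's voxels, back-transformed to r = tanh(mean z).
#'
#' @param voxels integer vector of the cluster's 1-based voxel ids.
#' @param stack output of [stack_fc_maps()].
#' @return list: `z` (per-subject mean Fisher-Z, named by subject),
#'   `r` (= tanh(z)).
#' @export
cluster_subject_fc <- function(voxels, stack) {
  if (length(voxels) == 0L) stop("empty cluster")
  z <- rowMeans(stack$Z[, voxels, drop = FALSE])
  names(z) <- stack$subject_ids
  list(z = z, r = tanh(z))
}

welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  (mean(x) - mean(y)) / sqrt(vx / nx + vy / ny)
}

#' Aging statistics for one cluster
#'
#' Mean coupling r in the younger and older split-half groups, a Welch
#' two-sample t on the subject-level Fisher-Z values (younger minus
#' older: positive t = coupling declines with age), the Spearman rank
#' correlation of coupling with age over all subjects, and the
#' small-effect filter flag (|mean r| > 0.1 in either group).
#'
#' @param voxels the cluster's 1-based voxel ids.
#' @param stack output of [stack_fc_maps()].
#' @param phenotypes the matching `phenotype_table`.
#' @param split a [split_half()] of the same phenotypes.
#' @return list of class `cluster_stats`: `mean_r_young`, `mean_r_old`,
#'   `t_delta_r`, `spearman_age`, `passes_effect_filter`, `subject_fc`.
#' @export
cluster_stats <- function(voxels, stack, phenotypes, split = split_half(phenotypes)) {
  fc <- cluster_subject_fc(voxels, stack)
  ids <- stack$subject_ids
  if (!setequal(union(split$young_ids, split$old_ids),
                setdiff(ids, split$excluded_id)))
    stop("split-half groups do not match the map stack's subjects")
  zy <- fc$z[match(split$young_ids, ids)]
  zo <- fc$z[match(split$old_ids, ids)]
  if (length(zy) < 2L || length(zo) < 2L) stop("split groups need >= 2 subjects")
  age <- phenotypes$age_years[match(ids, phenotypes$subject_id)]
  st <- list(mean_r_young = mean(tanh(zy)), mean_r_old = mean(tanh(zo)),
             t_delta_r = welch_t(zy, zo),
             spearman_age = stats::cor(fc$z, age, method = "spearman"),
             subject_fc = fc)
  st$passes_effect_filter <- effect_filter(st)
  class(st) <- "cluster_stats"
  st
}

#' Small-effect filter
#'
#' A cluster is reported only when its mean coupling exceeds a small
#' effect size (|r| > 0.1, strict) in the younger group, the older group,
#' or both.
#'
#' @param stats a `cluster_stats` (or any list with `mean_r_young`,
#'   `mean_r_old`).
#' @param threshold effect-size level on |mean r| (default 0.1, a small
#'   effect).
#' @return logical.
#' @export
effect_filter <- function(stats, threshold = 0.1) {
  abs(stats$mean_r_young) > threshold || abs(stats$mean_r_old) > threshold
}

#' Attach per-cluster aging statistics to a cluster set
#'
#' Computes [cluster_stats()] for every cluster and builds the report
#' table (one row per cluster, peak coordinates in world mm through the
#' grid affine). The result is "finalized" and accepted by
#' [write_cluster_table()].
#'
#' @param clusters a `cluster_set` from [permutation_cluster_fwe()] (or
#'   [conjunction_clusters()]; missing p_fwe is reported as NA).
#' @param stack output of [stack_fc_maps()].
#' @param phenotypes the matching `phenotype_table`.
#' @param split optional [split_half()]; derived from `phenotypes` by
#'   default.
#' @param apply_effect_filter drop clusters failing the small-effect
#'   filter (default TRUE).
#' @param effect_threshold filter level on |mean r| (default 0.1).
#' @return the `cluster_set` with `stats` (the report data.frame) and
#'   `per_cluster` (list of `cluster_stats`) attached.
#' @export
finalize_clusters <- function(clusters, stack, phenotypes,
                              split = split_half(phenotypes),
                              apply_effect_filter = TRUE,
                              effect_threshold = 0.1) {
  K <- clusters$n_clusters
  empty <- data.frame(cluster_id = integer(0), contrast = character(0),
                      n_voxels = integer(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_t = numeric(0), p_fwe = numeric(0),
                      mean_r_young = numeric(0), mean_r_old = numeric(0),
                      t_delta_r = numeric(0), spearman_age = numeric(0),
                      stringsAsFactors = FALSE)
  per <- list()
  rows <- list()
  if (K > 0L) {
    p_fwe <- if (is.null(clusters$p_fwe)) rep(NA_real_, K) else clusters$p_fwe
    for (k in seq_len(K)) {
      vox <- which(clusters$labels == k)
      st <- cluster_stats(vox, stack, phenotypes, split)
      if (apply_effect_filter && !effect_filter(st, effect_threshold)) next
      pk <- clusters$peaks[k, ]
      mm <- voxel_to_world(clusters$grid, cbind(pk$i0, pk$j0, pk$k0))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = k, contrast = clusters$pair$name,
        n_voxels = clusters$sizes[k],
        peak_x_mm = mm[1L], peak_y_mm = mm[2L], peak_z_mm = mm[3L],
        peak_t = pk$t, p_fwe = p_fwe[k],
        mean_r_young = st$mean_r_young, mean_r_old = st$mean_r_old,
        t_delta_r = st$t_delta_r, spearman_age = st$spearman_age,
        stringsAsFactors = FALSE)
      per[[as.character(k)]] <- st
    }
  }
  clusters$stats <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(clusters$stats) <- NULL
  clusters$per_cluster <- per
  clusters
}

#' Export age-versus-coupling scatter data per cluster
#'
#' Writes one TSV per finalized cluster with the per-subject coupling
#' against age — the data behind the scatter plots usually shown next to
#' significant clusters.
#'
#' @param clusters a finalized `cluster_set`.
#' @param phenotypes the matching `phenotype_table`.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_cluster_scatter <- function(clusters, phenotypes, dir) {
  if (is.null(clusters$per_cluster)) stop("cluster set is not finalized")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in names(clusters$per_cluster)) {
    fc <- clusters$per_cluster[[k]]$subject_fc
    df <- data.frame(subject_id = names(fc$z),
                     age_years = phenotypes$age_years[
                       match(names(fc$z), phenotypes$subject_id)],
                     fc_z = unname(fc$z), fc_r = unname(fc$r))
    p <- file.path(dir, sprintf("cluster%s_%s_scatter.tsv", k,
                                clusters$pair$name))
    write_tsv(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Hemispheric-difference analysis
#'
#' Tests whether any region couples more strongly with one seed than the
#' other: the paired per-subject difference D = Z_left - Z_right is fed
#' through the same covariate-adjusted group model, with the D main
#' effect playing the role of the FC main effect and the age covariate
#' tested by the same conjunction + permutation machinery.
#'
#' @param stack_left,stack_right outputs of [stack_fc_maps()] for the
#'   left and right seed, same subjects in the same order.
#' @param design a `group_design`.
#' @param pairs list of [contrast_pair()]s to test (default: all four).
#' @param ... further arguments to [permutation_cluster_fwe()]
#'   (`n_perm`, `forming_p`, `connectivity`, ..., `rng_seed`).
#' @return named list of `cluster_set`s, one per contrast pair, each with
#'   the D-based `stat_maps` attached.
#' @export
hemispheric_analysis <- function(stack_left, stack_right, design,
                                 pairs = lapply(c("pos_age_decrease",
                                                  "pos_age_increase",
                                                  "neg_age_decrease",
                                                  "neg_age_increase"),
                                                contrast_pair),
                                 ...) {
  if (!identical(stack_left$subject_ids, stack_right$subject_ids))
    stop("left/right map stacks contain different subjects")
  if (!same_grid(stack_left$grid, stack_right$grid))
    stop("left/right map stacks on different grids")
  dstack <- list(Z = stack_left$Z - stack_right$Z,
                 mask = stack_left$mask & stack_right$mask,
                 grid = stack_left$grid, subject_ids = stack_left$subject_ids)
  out <- lapply(pairs, function(p)
    permutation_cluster_fwe(dstack, design, p, ...))
  names(out) <- vapply(pairs, `[[`, "", "name")
  out
}

#' Interhemispheric seed coupling versus age
#'
#' Correlates each subject's left and right seed eigenvariates, Fisher-Z
#' transforms the coupling, and summarizes its age dependence with the
#' same statistics reported per cluster (split-half means, Welch t,
#' Spearman correlation with age).
#'
#' @param bolds named list of preprocessed [bold4d()] objects (names =
#'   subject ids).
#' @param atlas the cohort [label_volume()].
#' @param phenotypes the matching `phenotype_table`.
#' @return list: `subject_r`, `subject_z` (named per-subject vectors),
#'   `mean_r_young`, `mean_r_old`, `t_delta_r`, `spearman_age`,
#'   `spearman_p`.
#' @export
interhemispheric_fc_vs_age <- function(bolds, atlas, phenotypes) {
  ids <- names(bolds)
  if (is.null(ids) || !setequal(ids, phenotypes$subject_id))
    stop("bolds must be named by the phenotype table's subject ids")
  z <- vapply(bolds, function(b) {
    l <- seed_series(b, atlas, "left")
    r <- seed_series(b, atlas, "right")
    rr <- stats::cor(l$values, r$values)
    atanh(pmin(pmax(rr, -fisher_z_clip), fisher_z_clip))
  }, numeric(1L))
  age <- phenotypes$age_years[match(ids, phenotypes$subject_id)]
  split <- split_half(phenotypes)
  zy <- z[match(split$young_ids, ids)]
  zo <- z[match(split$old_ids, ids)]
  sp <- suppressWarnings(stats::cor.test(z, age, method = "spearman"))
  list(subject_r = tanh(z), subject_z = z,
       mean_r_young = mean(tanh(zy)), mean_r_old = mean(tanh(zo)),
       t_delta_r = welch_t(zy, zo),
       spearman_age = unname(sp$estimate), spearman_p = sp$p.value)
}
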