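#' Extract the first eigenvariate of a voxel set
#'
#' The representative time series of a region: the first left singular
#' vector of the mean-centered T x V matrix of its voxel series, rescaled
#' to unit variance, sign-aligned so that it correlates non-negatively
#' with the spatial mean of the region (first nonzero element forced
#' positive when the spatial mean is degenerate).
#'
#' @param bold a [bold4d()].
#' @param voxels integer vector of 1-based linear voxel ids.
#' @param source label recorded on the result ("bilateral", "left",
#'   "right").
#' @return list of class `seed_series`: `values` (length T, unit
#'   variance), `source`, `n_voxels_used`.
#' @export
extract_eigenvariate <- function(bold, voxels, source = "bilateral") {
  if (length(voxels) < 1L) stop("seed has no voxels")
  M <- bold$data[, voxels, drop = FALSE]
  M <- sweep(M, 2L, colMeans(M))
  if (max(abs(M)) < 1e-12)
    stop("all seed voxels are constant; eigenvariate undefined")
  sv <- svd(M, nu = 1L, nv = 0L)
  u <- sv$u[, 1L]
  spatial_mean <- rowMeans(M)
  al <- sum(u * spatial_mean)
  if (al < 0) {
    u <- -u
  } else if (al == 0) {
    nz <- which(abs(u) > 0)[1L]
    if (length(nz) && u[nz] < 0) u <- -u
  }
  u <- u / stats::sd(u)
  structure(list(values = u, source = source, n_voxels_used = ncol(M)),
            class = "seed_series")
}

#' Seed time series from an atlas
#'
#' `collapse_bilateral_seed()` computes the eigenvariate over the union
#' of left and right seed voxels (the common bilateral seed);
#' `seed_series()` dispatches on `source` to bilateral/left/right.
#'
#' @param bold a [bold4d()].
#' @param atlas a [label_volume()] with `seed_left`/`seed_right` roles.
#' @param method how to collapse the two ROIs: the eigenvariate of the
#'   voxel union (default, the primary definition) or the mean of the two
#'   per-hemisphere eigenvariates (sensitivity alternative), restandardized.
#' @return a `seed_series`.
#' @export
collapse_bilateral_seed <- function(bold, atlas,
                                    method = c("eigenvariate_union",
                                               "mean_of_eigenvariates")) {
  method <- match.arg(method)
  l <- label_voxels(atlas, "seed_left")
  r <- label_voxels(atlas, "seed_right")
  if (length(l) == 0L || length(r) == 0L) stop("both seed ROIs must be non-empty")
  if (method == "eigenvariate_union")
    return(extract_eigenvariate(bold, union(l, r), source = "bilateral"))
  m <- (extract_eigenvariate(bold, l, "left")$values +
          extract_eigenvariate(bold, r, "right")$values) / 2
  structure(list(values = m / stats::sd(m), source = "bilateral",
                 n_voxels_used = length(union(l, r))),
            class = "seed_series")
}

#' @rdname collapse_bilateral_seed
#' @param source which seed: "bilateral" (union of both ROIs), "left", or
#'   "right".
#' @export
seed_series <- function(bold, atlas, source = c("bilateral", "left", "right")) {
  source <- match.arg(source)
  if (source == "bilateral") return(collapse_bilateral_seed(bold, atlas))
  vox <- label_voxels(atlas, paste0("seed_", source))
  if (length(vox) == 0L) stop("seed ROI '", source, "' is empty")
  extract_eigenvariate(bold, vox, source = source)
}

fisher_z_clip <- 1 - 1e-7

#' Voxel-wise Fisher-Z connectivity map
#'
#' Pearson-correlates the seed series with every in-mask voxel series and
#' maps r through Fisher's Z = atanh(r), clipping |r| at 1 - 1e-7 to keep
#' the map finite. Zero-variance voxels get z = 0 and are removed from
#' the mask.
#'
#' @param bold a preprocessed [bold4d()].
#' @param seed a `seed_series` of matching length.
#' @param mask logical vector (length V) of analysis voxels, e.g.
#'   [analysis_mask()].
#' @return list of class `fc_map`: `grid`, `z` (length V, 0 outside
#'   mask), `mask`, `subject_id`, `seed_source`.
#' @export
fc_zmap <- function(bold, seed, mask) {
  Tt <- n_timepoints(bold)
  if (length(seed$values) != Tt)
    stop("seed length (", length(seed$values), ") does not match BOLD length (",
         Tt, ")")
  mask <- as.logical(mask)
  if (length(mask) != ncol(bold$data)) stop("mask length does not match grid")
  if (!any(mask)) stop("empty analysis mask")
  idx <- which(mask)
  Y <- bold$data[, idx, drop = FALSE]
  s <- seed$values - mean(seed$values)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ssd <- sqrt(colSums(Yc^2))
  ok <- ssd > 1e-12
  r <- numeric(length(idx))
  r[ok] <- as.vector(crossprod(Yc[, ok, drop = FALSE], s)) /
    (ssd[ok] * sqrt(sum(s^2)))
  r <- pmin(pmax(r, -fisher_z_clip), fisher_z_clip)
  z <- numeric(length(mask))
  z[idx[ok]] <- atanh(r[ok])
  mask[idx[!ok]] <- FALSE
  structure(list(grid = bold$grid, z = z, mask = mask,
                 subject_id = bold$subject_id, seed_source = seed$source),
            class = "fc_map")
}

#' Stack per-subject FC maps into a subjects x voxels matrix
#'
#' @param zmaps list of `fc_map` objects on one grid, one per subject.
#' @return list: `Z` (N x V matrix), `mask` (intersection of subject
#'   masks), `grid`, `subject_ids`.
#' @export
stack_fc_maps <- function(zmaps) {
  stopifnot(length(zmaps) >= 1L)
  grid <- zmaps[[1L]]$grid
  for (m in zmaps) if (!same_grid(m$grid, grid)) stop("FC maps on different grids")
  Z <- do.call(rbind, lapply(zmaps, `[[`, "z"))
  mask <- Reduce(`&`, lapply(zmaps, `[[`, "mask"))
  list(Z = Z, mask = mask, grid = grid,
       subject_ids = vapply(zmaps, `[[`, "", "subject_id"))
}

#' Write an FC map as NIfTI
#'
#' @param fc an `fc_map`.
#' @param path output path.
#' @export
write_fc_map <- function(fc, path) {
  write_nifti_with_grid(array(fc$z, fc$grid$shape), fc$grid, path)
}
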