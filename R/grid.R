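#' Image grid geometry
#'
#' A `volume_grid` bundles the spatial/temporal geometry shared by all
#' volumes of a study: voxel counts per axis, voxel size in mm, the 4x4
#' voxel-to-world affine, and the repetition time (TR) of the time axis.
#' Voxel indices are 0-based when mapped through the affine; reported
#' coordinates are always world mm.
#'
#' @param shape integer vector of length 3, voxels per spatial axis.
#' @param voxel_size_mm numeric length 3, voxel edge lengths in mm.
#' @param affine 4x4 voxel-index-to-world-mm matrix; defaults to a scaled
#'   identity centred on the volume.
#' @param tr_seconds repetition time of the time axis in seconds.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm, affine = NULL, tr_seconds = NA_real_) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    # centre the volume on the world origin
    affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(colnorm - voxel_size_mm) > 1e-6))
    stop("voxel_size_mm must equal the column norms of the affine 3x3 block")
  if (!is.na(tr_seconds) && tr_seconds <= 0)
    stop("tr_seconds must be positive")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine, tr_seconds = as.numeric(tr_seconds)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, %s mm, TR %s s\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              format(x$tr_seconds)))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param grid a [volume_grid()].
#' @param index0 matrix (n x 3) or vector of 0-based voxel indices.
#' @return n x 3 matrix of world-space mm coordinates.
#' @export
voxel_to_world <- function(grid, index0) {
  idx <- matrix(as.numeric(index0), ncol = 3L)
  xyz1 <- cbind(idx, 1)
  out <- xyz1 %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

## linear voxel id (1-based, x fastest) <-> 0-based (i,j,k)
voxel_id_to_index0 <- function(grid, vid) {
  v <- as.integer(vid) - 1L
  nx <- grid$shape[1L]; ny <- grid$shape[2L]
  cbind(v %% nx, (v %/% nx) %% ny, v %/% (nx * ny))
}

index0_to_voxel_id <- function(grid, idx0) {
  nx <- grid$shape[1L]; ny <- grid$shape[2L]
  as.integer(idx0[, 1L] + nx * (idx0[, 2L] + ny * idx0[, 3L]) + 1L)
}

#' Construct an in-memory 4D BOLD series
#'
#' Internally the series is stored time-major: a T x V matrix whose columns
#' enumerate voxels in column-major (x-fastest) spatial order.
#'
#' @param data T x V numeric matrix, or a T x X x Y x Z array.
#' @param grid a [volume_grid()] with positive `tr_seconds`.
#' @param subject_id subject identifier string.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, grid, subject_id = "unknown") {
  if (is.array(data) && length(dim(data)) == 4L) {
    stopifnot(all(dim(data)[2:4] == grid$shape))
    data <- matrix(data, nrow = dim(data)[1L])
  }
  data <- as.matrix(data)
  if (ncol(data) != n_voxels(grid))
    stop("data has ", ncol(data), " voxels but grid implies ", n_voxels(grid))
  if (nrow(data) < 2L) stop("BOLD series needs at least 2 time points")
  if (!all(is.finite(data))) stop("BOLD data must be finite")
  new_bold4d(data, grid, subject_id)
}

## internal constructor: trusted inputs, no validation pass
new_bold4d <- function(data, grid, subject_id) {
  structure(list(grid = grid, data = data, subject_id = as.character(subject_id)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("bold4d '%s': T=%d, grid %s, TR %s s\n", x$subject_id,
              nrow(x$data), paste(x$grid$shape, collapse = "x"),
              format(x$grid$tr_seconds)))
  invisible(x)
}

n_timepoints <- function(bold) nrow(bold$data)

#' Construct a label volume (ROI / tissue atlas)
#'
#' @param labels X x Y x Z integer array, or integer vector of length V
#'   (column-major order); 0 denotes unlabeled voxels.
#' @param grid a [volume_grid()].
#' @param legend data.frame with columns `label` (integer) and `role`
#'   (character: "gm", "wm", "csf", "seed_left", "seed_right", "effect").
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, legend) {
  labels <- as.integer(labels)
  if (length(labels) != n_voxels(grid))
    stop("labels length does not match grid")
  if (any(labels < 0L)) stop("labels must be non-negative")
  legend <- as.data.frame(legend)
  stopifnot(all(c("label", "role") %in% names(legend)))
  present <- setdiff(unique(labels), 0L)
  missing <- setdiff(present, legend$label)
  if (length(missing))
    stop("labels without legend entry: ", paste(missing, collapse = ", "))
  obj <- structure(list(grid = grid, labels = labels, legend = legend),
                   class = "label_volume")
  if (length(label_voxels(obj, "seed_left")) == 0L ||
      length(label_voxels(obj, "seed_right")) == 0L)
    stop("seed_left and seed_right must both be non-empty")
  obj
}

#' Voxel ids carrying a given atlas role
#'
#' @param atlas a [label_volume()].
#' @param role one or more legend roles.
#' @return integer vector of 1-based linear voxel ids.
#' @export
label_voxels <- function(atlas, role) {
  labs <- atlas$legend$label[atlas$legend$role %in% role]
  which(atlas$labels %in% labs)
}

#' Analysis mask for connectivity maps
#'
#' Gray matter plus seed and effect-region voxels (seeds are retained in
#' the maps; WM/CSF compartments are excluded).
#'
#' @param atlas a [label_volume()].
#' @return logical vector of length V.
#' @export
analysis_mask <- function(atlas) {
  keep <- label_voxels(atlas, c("gm", "seed_left", "seed_right", "effect"))
  mask <- logical(n_voxels(atlas$grid))
  mask[keep] <- TRUE
  mask
}
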