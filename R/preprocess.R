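#' Preprocessing configuration
#'
#' @param n_discard initial volumes dropped to let T1 saturation settle
#'   (default 4).
#' @param fwhm_mm full-width-at-half-maximum of the spatial Gaussian
#'   smoothing kernel in mm (default 5; 0 disables smoothing).
#' @param band_hz length-2 pass band in Hz (default 0.01-0.08).
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(n_discard = 4L, fwhm_mm = 5, band_hz = c(0.01, 0.08)) {
  stopifnot(n_discard >= 0L, fwhm_mm >= 0, length(band_hz) == 2L,
            band_hz[1L] > 0, band_hz[1L] < band_hz[2L])
  structure(list(n_discard = as.integer(n_discard), fwhm_mm = fwhm_mm,
                 band_hz = as.numeric(band_hz)),
            class = "preproc_config")
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` time points of a BOLD series (and, when
#' given, the matching motion-table rows) to remove T1 saturation
#' transients.
#'
#' @param bold a [bold4d()].
#' @param n_discard number of initial volumes to drop.
#' @param motion optional paired `motion_table`; its leading rows are
#'   dropped identically.
#' @return the truncated `bold4d`, or `list(bold, motion)` when a motion
#'   table is supplied.
#' @export
discard_initial_volumes <- function(bold, n_discard = 4L, motion = NULL) {
  Tt <- n_timepoints(bold)
  if (Tt <= n_discard)
    stop("cannot discard ", n_discard, " volumes from a series of length ", Tt)
  keep <- seq.int(n_discard + 1L, Tt)
  out <- new_bold4d(bold$data[keep, , drop = FALSE], bold$grid, bold$subject_id)
  if (is.null(motion)) return(out)
  if (nrow(motion) != Tt)
    stop("motion table has ", nrow(motion), " rows but BOLD series has ", Tt)
  list(bold = out, motion = motion_table(unclass(motion)[keep, , drop = FALSE]))
}

#' Spatial Gaussian smoothing
#'
#' Separable per-volume Gaussian with per-axis sigma (in voxels)
#' `fwhm_mm / (sqrt(8 log 2) * voxel_size_mm[axis])` and reflect-padded
#' boundaries. `fwhm_mm = 0` is the identity.
#'
#' @param bold a [bold4d()].
#' @param fwhm_mm kernel FWHM in mm.
#' @return smoothed `bold4d`.
#' @export
smooth_fwhm <- function(bold, fwhm_mm = 5) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(bold)
  sigma <- fwhm_mm / (sqrt(8 * log(2)) * bold$grid$voxel_size_mm)
  out <- .gauss_smooth_cpp(bold$data, bold$grid$shape, sigma)
  new_bold4d(out, bold$grid, bold$subject_id)
}

#' Build the nuisance design matrix
#'
#' Columns: intercept; the six realignment parameters; their backward
#' differences (first row 0); and the mean time series of the gray-matter,
#' white-matter and CSF compartments (spatial mean over each tissue class
#' at every time point). All non-intercept columns are mean-centered.
#' Zero-variance columns (e.g. the derivative of a constant motion trace)
#' are flagged and dropped with a warning.
#'
#' @param motion `motion_table` already truncated to the analysis window.
#' @param bold the (discarded, smoothed) [bold4d()] the tissue means are
#'   read from.
#' @param tissues a [label_volume()] with non-empty gm/wm/csf classes.
#' @return list of class `nuisance_design`: `matrix` (T x K),
#'   `column_names`, `rank`, `dropped` (names of removed columns).
#' @export
build_nuisance_design <- function(motion, bold, tissues) {
  Tt <- n_timepoints(bold)
  if (nrow(motion) != Tt)
    stop("motion rows (", nrow(motion), ") must match BOLD length (", Tt, ")")
  if (!same_grid(bold$grid, tissues$grid)) stop("atlas grid mismatch")
  mot <- unclass(motion)
  dmot <- rbind(0, diff(mot))
  tiss <- sapply(c("gm", "wm", "csf"), function(cls) {
    vox <- label_voxels(tissues, cls)
    if (length(vox) == 0L) stop("empty tissue class: ", cls)
    rowMeans(bold$data[, vox, drop = FALSE])
  })
  X <- cbind(mot, dmot, tiss)
  colnames(X) <- c(paste0("motion", 1:6), paste0("dmotion", 1:6),
                   "gm", "wm", "csf")
  X <- scale(X, center = TRUE, scale = FALSE)
  sds <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[sds < 1e-12]
  if (length(dropped)) {
    warning("dropping zero-variance nuisance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  X <- cbind(intercept = 1, X)
  structure(list(matrix = unname(X), column_names = colnames(X),
                 rank = qr(X)$rank, dropped = dropped),
            class = "nuisance_design")
}

#' Remove nuisance variance by least squares
#'
#' Replaces every voxel series with its residual against the nuisance
#' design. The intercept is part of the design, so residuals are
#' mean-zero and orthogonal to every retained column.
#'
#' @param bold a [bold4d()].
#' @param design a `nuisance_design` (or plain T x K matrix) with as many
#'   rows as the series has time points.
#' @return residualized `bold4d`.
#' @export
residualize <- function(bold, design) {
  X <- if (inherits(design, "nuisance_design")) design$matrix else as.matrix(design)
  if (nrow(X) != n_timepoints(bold))
    stop("design rows must equal the number of time points")
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("nuisance design is rank-deficient after column dropping")
  res <- qr.resid(qrx, bold$data)
  new_bold4d(res, bold$grid, bold$subject_id)
}

## Orthonormal basis of the kept DFT bins: one cosine and one sine column
## per positive in-band frequency (plus the Nyquist cosine when kept).
## Projecting onto this basis is algebraically identical to zeroing the
## complementary FFT coefficients, but runs as two BLAS products.
bandpass_basis <- function(Tt, tr, band) {
  nyq <- 1 / (2 * tr)
  if (band[1L] <= 0 || band[2L] > nyq + 1e-12)
    stop(sprintf("band [%g, %g] Hz must lie inside (0, Nyquist=%g] for TR %g s",
                 band[1L], band[2L], nyq, tr))
  k <- seq_len(floor(Tt / 2))
  f <- k / (Tt * tr)
  k <- k[f >= band[1L] - 1e-12 & f <= band[2L] + 1e-12]
  if (length(k) == 0L) return(matrix(0, Tt, 0L))
  t_idx <- seq_len(Tt) - 1L
  cols <- lapply(k, function(kk) {
    ang <- 2 * pi * kk * t_idx / Tt
    if (2L * kk == Tt) list(cos(ang) / sqrt(Tt))       # Nyquist bin
    else list(cos(ang) / sqrt(Tt / 2), sin(ang) / sqrt(Tt / 2))
  })
  do.call(cbind, unlist(cols, recursive = FALSE))
}

## ideal DFT band-pass of a T x V matrix; retains bins with
## low <= f <= high (DC excluded by low > 0), zero-phase, real output
bandpass_matrix <- function(x, tr, band) {
  B <- bandpass_basis(nrow(x), tr, band)
  B %*% crossprod(B, x)
}

#' Temporal band-pass filter
#'
#' Ideal discrete-Fourier filter: Fourier coefficients with frequency
#' inside `band_hz` are kept exactly, all others (including DC) are
#' zeroed; zero-phase by construction.
#'
#' @param bold a [bold4d()] with at least 20 time points.
#' @param band_hz length-2 pass band in Hz, inside (0, Nyquist).
#' @return filtered `bold4d`.
#' @export
bandpass <- function(bold, band_hz = c(0.01, 0.08)) {
  if (n_timepoints(bold) < 20L) stop("band-pass needs at least 20 time points")
  new_bold4d(bandpass_matrix(bold$data, bold$grid$tr_seconds, band_hz),
         bold$grid, bold$subject_id)
}

#' Run the per-subject preprocessing chain
#'
#' Fixed order: discard initial volumes, spatial smoothing, nuisance
#' regression (motion, motion derivatives, tissue means), temporal
#' band-pass. The order is part of the method definition and cannot be
#' permuted.
#'
#' @param bold a [bold4d()].
#' @param motion the subject's `motion_table` (full length, pre-discard).
#' @param atlas a [label_volume()] with gm/wm/csf classes.
#' @param config a [preproc_config()].
#' @return preprocessed `bold4d`.
#' @export
preprocess_subject <- function(bold, motion, atlas, config = preproc_config()) {
  dm <- discard_initial_volumes(bold, config$n_discard, motion)
  sm <- smooth_fwhm(dm$bold, config$fwhm_mm)
  nd <- build_nuisance_design(dm$motion, sm, atlas)
  rs <- residualize(sm, nd)
  bandpass(rs, config$band_hz)
}
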