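#' Read a 4D BOLD NIfTI file
#'
#' The grid is populated from the NIfTI header: affine from the
#' sform/qform, voxel sizes from pixdim, TR from the 4th pixdim entry.
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz) with 4 dimensions.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return A [bold4d()].
#' @export
read_bold <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("BOLD file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4-dimensional BOLD image, got ", length(d),
         " dimensions in ", path)
  hdr <- RNifti::niftiHeader(img)
  tr <- hdr$pixdim[5L]
  if (!is.finite(tr) || tr <= 0)
    stop("non-positive TR in pixdim[4] of ", path)
  aff <- matrix(as.vector(RNifti::xform(img)), 4L, 4L)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- volume_grid(d[1:3], vox, affine = aff, tr_seconds = tr)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  # reorder to time-major: T x V
  dat <- matrix(aperm(as.array(img), c(4L, 1L, 2L, 3L)), nrow = d[4L])
  bold4d(dat, grid, subject_id)
}

#' Write a 4D BOLD series as NIfTI-1
#'
#' @param bold a [bold4d()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path) {
  Tt <- n_timepoints(bold)
  arr <- aperm(array(bold$data, c(Tt, bold$grid$shape)), c(2L, 3L, 4L, 1L))
  write_nifti_with_grid(arr, bold$grid, path, tr = bold$grid$tr_seconds)
}

write_nifti_with_grid <- function(arr, grid, path, tr = NA_real_) {
  img <- RNifti::asNifti(arr)
  pd <- c(grid$voxel_size_mm, if (is.na(tr)) 1 else tr)
  RNifti::pixdim(img) <- pd[seq_len(length(dim(arr)))]
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume (ROI/tissue atlas) and its legend
#'
#' @param path path to a 3D integer-valued NIfTI file.
#' @param legend data.frame (label, role) or path to a TSV with those
#'   columns.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, legend) {
  if (!file.exists(path)) stop("label volume not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("label volume must be 3-dimensional")
  aff <- matrix(as.vector(RNifti::xform(img)), 4L, 4L)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- volume_grid(d, vox, affine = aff, tr_seconds = NA_real_)
  if (is.character(legend))
    legend <- utils::read.delim(legend, stringsAsFactors = FALSE)
  label_volume(as.integer(round(as.array(img))), grid, legend)
}

#' Write a label volume and its legend
#'
#' @param atlas a [label_volume()].
#' @param path output NIfTI path; the legend is written next to it as
#'   `<path>_legend.tsv`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(atlas, path) {
  arr <- array(as.numeric(atlas$labels), atlas$grid$shape)
  write_nifti_with_grid(arr, atlas$grid, path)
  write_tsv(atlas$legend, paste0(sub("\\.nii(\\.gz)?$", "", path), "_legend.tsv"))
  invisible(path)
}

#' Read an SPM-style realignment-parameter (motion) file
#'
#' Whitespace-delimited T x 6 table: three translations (mm) followed by
#' three rotations (radians).
#'
#' @param path path to the motion file.
#' @return T x 6 numeric matrix with class `motion_table`.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop("motion file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_table(m)
}

#' @rdname read_motion
#' @param m T x 6 numeric matrix.
#' @export
motion_table <- function(m) {
  m <- unname(as.matrix(m))
  if (ncol(m) != 6L) stop("motion table must have 6 columns, got ", ncol(m))
  if (!all(is.finite(m))) stop("motion table must be finite")
  storage.mode(m) <- "double"
  class(m) <- c("motion_table", class(m))
  m
}

#' @rdname read_motion
#' @param motion a `motion_table`.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 10, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

phenotype_required_cols <- c("subject_id", "age_years", "sex", "site")

#' Read a phenotype table
#'
#' Tab-separated, one row per subject, with columns `subject_id`,
#' `age_years`, `sex`, `site` and optionally `bold_path`, `motion_path`.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `phenotype_table`, rows in file order, with
#'   `sex` and `site` as factors.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  phenotype_table(df)
}

#' @rdname read_phenotypes
#' @param df data.frame with the required columns.
#' @export
phenotype_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(phenotype_required_cols, names(df))
  if (length(missing))
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup))
    stop("duplicated subject_id: ", paste(unique(dup), collapse = ", "))
  age <- suppressWarnings(as.numeric(df$age_years))
  if (anyNA(age))
    stop("unparseable age_years in row(s): ",
         paste(which(is.na(age)), collapse = ", "))
  if (any(age <= 0)) stop("age_years must be positive")
  df$age_years <- age
  df$sex <- factor(df$sex)
  df$site <- factor(df$site)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(df, path) {
  write_tsv(as.data.frame(df), path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a finalized cluster table
#'
#' One row per cluster, TSV, mirroring the study's per-cluster report:
#' extent, peak location in world mm (via the grid affine), corrected
#' p-value, split-half mean coupling, Welch t on the coupling difference,
#' and Spearman correlation with age.
#'
#' @param clusters a finalized `cluster_set` (see [finalize_clusters()]),
#'   or a data.frame already in table form.
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  tab <- if (is.data.frame(clusters)) clusters else cluster_table(clusters)
  num <- vapply(tab, is.numeric, logical(1L))
  out <- tab
  out[num] <- lapply(tab[num], function(x) formatC(x, format = "fg", digits = 10))
  write_tsv(out, path)
  invisible(tab)
}

#' Extract the report table from a finalized cluster set
#'
#' @param clusters a `cluster_set` whose per-cluster statistics have been
#'   attached by [finalize_clusters()].
#' @return data.frame with columns cluster_id, contrast, n_voxels,
#'   peak_x_mm, peak_y_mm, peak_z_mm, peak_t, p_fwe, mean_r_young,
#'   mean_r_old, t_delta_r, spearman_age.
#' @export
cluster_table <- function(clusters) {
  if (!inherits(clusters, "cluster_set")) stop("not a cluster_set")
  if (is.null(clusters$stats))
    stop("cluster set is not finalized; run finalize_clusters() first")
  clusters$stats
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
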