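#' Full-run configuration
#'
#' Bundles every knob of the end-to-end pipeline. Thresholds follow the
#' study defaults: voxel-forming p 0.001, cluster-level alpha 0.05 with
#' an exploratory liberal threshold of 0.1.
#'
#' @param cohort_dir directory with `phenotypes.tsv`, `atlas.nii.gz` (+
#'   legend TSV) and the per-subject files the phenotype table points to.
#' @param out_dir output directory for maps, tables, manifest and log.
#' @param preproc a [preproc_config()].
#' @param seed_source "bilateral", "left" or "right".
#' @param contrasts character vector of [contrast_pair()] names to test.
#' @param n_perm permutations for the cluster-level correction.
#' @param forming_p,cluster_alpha,liberal_alpha inference thresholds.
#' @param connectivity cluster connectivity (6/18/26).
#' @param effect_threshold small-effect filter level on |mean r|.
#' @param rng_seed integer root seed; per-stage streams are derived from
#'   it by stable hashing, so subject order never matters.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_dir, out_dir,
                       preproc = preproc_config(),
                       seed_source = "bilateral",
                       contrasts = c("pos_age_decrease", "pos_age_increase",
                                     "neg_age_decrease", "neg_age_increase"),
                       n_perm = 1000L, forming_p = 0.001,
                       cluster_alpha = 0.05, liberal_alpha = 0.1,
                       connectivity = 26L, effect_threshold = 0.1,
                       rng_seed = 1L) {
  stopifnot(forming_p > 0, forming_p < 1, cluster_alpha > 0, cluster_alpha < 1,
            liberal_alpha > 0, liberal_alpha < 1)
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 preproc = preproc, seed_source = seed_source,
                 contrasts = contrasts, n_perm = as.integer(n_perm),
                 forming_p = forming_p, cluster_alpha = cluster_alpha,
                 liberal_alpha = liberal_alpha,
                 connectivity = as.integer(connectivity),
                 effect_threshold = effect_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `preproc` may be a
#' nested mapping with `n_discard`, `fwhm_mm`, `band_hz`.
#'
#' @param path YAML file.
#' @param cohort_dir,out_dir optional overrides.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, cohort_dir = NULL, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(cohort_dir)) y$cohort_dir <- cohort_dir
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(y$preproc)) y$preproc <- do.call(preproc_config, y$preproc)
  do.call(run_config, y)
}

#' Load a cohort directory
#'
#' @param dir cohort directory written by [write_cohort()] (or laid out
#'   the same way).
#' @return list: `phenotypes`, `atlas`, `bolds`, `motions` (named lists).
#' @export
read_cohort <- function(dir) {
  phen <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  if (is.null(phen$bold_path) || is.null(phen$motion_path))
    stop("phenotype table must carry bold_path and motion_path columns")
  atlas <- read_label_volume(file.path(dir, "atlas.nii.gz"),
                             file.path(dir, "atlas_legend.tsv"))
  bolds <- lapply(seq_len(nrow(phen)), function(i)
    read_bold(file.path(dir, phen$bold_path[i]), phen$subject_id[i]))
  motions <- lapply(seq_len(nrow(phen)), function(i)
    read_motion(file.path(dir, phen$motion_path[i])))
  names(bolds) <- names(motions) <- phen$subject_id
  list(phenotypes = phen, atlas = atlas, bolds = bolds, motions = motions)
}

pipeline_log <- function(con, level, stage, msg) {
  line <- sprintf("%s [%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, stage, msg)
  writeLines(line, con)
  message(line)
}

#' Run the whole pipeline on a cohort directory
#'
#' Stages, in fixed order: load cohort, per-subject preprocessing
#' (discard, smooth, nuisance regression, band-pass), seed eigenvariate
#' and Fisher-Z connectivity maps, group GLM with conjunction contrasts
#' and permutation cluster-level FWE, per-cluster aging statistics with
#' the small-effect filter, and the cluster report table. Identical
#' config and seed produce a byte-identical cluster table.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; side effects: per-subject
#'   z-map NIfTIs, t-map NIfTIs, `cluster_table.tsv`, `manifest.yaml`,
#'   `run.log` under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)

  cohort <- tryCatch(read_cohort(config$cohort_dir),
                     error = function(e) stop("stage load: ", conditionMessage(e)))
  phen <- cohort$phenotypes
  pipeline_log(logf, "INFO", "load", sprintf("%d subjects", nrow(phen)))

  zmaps <- vector("list", nrow(phen))
  for (i in seq_len(nrow(phen))) {
    sid <- phen$subject_id[i]
    res <- tryCatch({
      pp <- preprocess_subject(cohort$bolds[[sid]], cohort$motions[[sid]],
                               cohort$atlas, config$preproc)
      seed <- seed_series(pp, cohort$atlas, config$seed_source)
      fc_zmap(pp, seed, analysis_mask(cohort$atlas))
    }, error = function(e)
      stop("stage preprocess/fc, subject ", sid, ": ", conditionMessage(e)))
    zmaps[[i]] <- res
    write_fc_map(res, file.path(out, sprintf("%s_%s_zmap.nii.gz", sid,
                                             config$seed_source)))
    pipeline_log(logf, "INFO", "fc", sid)
  }
  stack <- stack_fc_maps(zmaps)
  design <- build_group_design(phen)
  split <- split_half(phen)

  tabs <- list()
  for (cname in config$contrasts) {
    pair <- contrast_pair(cname)
    cs <- tryCatch(
      permutation_cluster_fwe(stack, design, pair, n_perm = config$n_perm,
                              forming_p = config$forming_p,
                              cluster_alpha = config$cluster_alpha,
                              liberal_alpha = config$liberal_alpha,
                              connectivity = config$connectivity,
                              rng_seed = derive_seed(config$rng_seed,
                                                     "group", cname)),
      error = function(e) stop("stage group, contrast ", cname, ": ",
                               conditionMessage(e)))
    cs <- finalize_clusters(cs, stack, phen, split,
                            effect_threshold = config$effect_threshold)
    if (cs$n_clusters > 0L)
      write_cluster_scatter(cs, phen, file.path(out, "scatter"))
    keep <- cs$stats[!is.na(cs$stats$p_fwe) &
                       cs$stats$p_fwe < config$liberal_alpha, , drop = FALSE]
    tabs[[cname]] <- keep
    pipeline_log(logf, "INFO", "group",
                 sprintf("%s: %d cluster(s), %d significant",
                         cname, cs$n_clusters, sum(cs$significant)))
    if (cname == config$contrasts[[1L]]) {
      write_nifti_with_grid(array(cs$maps$t_main, stack$grid$shape),
                            stack$grid, file.path(out, "tmap_main.nii.gz"))
      write_nifti_with_grid(array(cs$maps$t_age, stack$grid$shape),
                            stack$grid, file.path(out, "tmap_age.nii.gz"))
    }
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  write_cluster_table(table, file.path(out, "cluster_table.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("stnfc")),
    rng_seed = config$rng_seed,
    config = config_echo(config),
    checksums = as.list(tools::md5sum(file.path(out, "cluster_table.tsv"))))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  pipeline_log(logf, "INFO", "report",
               sprintf("%d cluster(s) in final table", nrow(table)))
  invisible(out)
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$preproc <- unclass(cfg$preproc)
  cfg
}
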