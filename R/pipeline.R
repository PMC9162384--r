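#' Pipeline configuration
#'
#' One object carries every stage parameter, so a full analysis is a pure
#' function of (config, seed): cohort simulation, per-metric group
#' statistics, clinical correlation with outlier screening, the
#' extended-NBS sweep, and per-region classification.
#'
#' @param out_dir output directory
#' @param seed master seed; stage seeds derive from it via [derive_seed()]
#' @param cohort a [cohort_spec()] (its seed is overridden by `seed`)
#' @param stages named logical vector toggling `stats`, `nbs`, `classify`
#' @param alpha_discovery FDR level declaring a region significantly
#'   different (default 0.001)
#' @param alpha_feature FDR level admitting a metric into a region's
#'   classification features (default 0.05)
#' @param corr_alpha raw-p level selecting clinical correlations (0.001)
#' @param outlier_k robust z cutoff for Q-Q screening (default 3.5)
#' @param manual_exclusions subject ids excluded from all statistics and
#'   classification
#' @param nbs_thresholds edge p-value ladder for the sweep
#' @param n_perm permutations for the NBS null (default 5000)
#' @param nbs_alpha component significance level (default 0.05)
#' @param nbs_feature_threshold sweep threshold whose components feed the
#'   classifier (default 0.0010)
#' @param c_grid SVM cost grid
#' @param accuracy_cutoff strict accuracy cutoff for the reported top
#'   regions (default 0.90)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("msanet_run_"),
                            seed = 1L,
                            cohort = cohort_spec(seed = seed),
                            stages = c(stats = TRUE, nbs = TRUE,
                                       classify = TRUE),
                            alpha_discovery = 0.001,
                            alpha_feature = 0.05,
                            corr_alpha = 0.001,
                            outlier_k = 3.5,
                            manual_exclusions = character(),
                            nbs_thresholds = seq(1e-4, 1e-3, by = 1e-4),
                            n_perm = 5000L,
                            nbs_alpha = 0.05,
                            nbs_feature_threshold = 0.0010,
                            c_grid = default_c_grid(),
                            accuracy_cutoff = 0.90) {
  cohort$seed <- as.integer(seed)
  validate_cohort_spec(cohort)
  stopifnot(alpha_discovery > 0, alpha_discovery < 1,
            alpha_feature > 0, alpha_feature < 1,
            corr_alpha > 0, corr_alpha < 1, outlier_k > 0,
            n_perm >= 1, nbs_alpha > 0, nbs_alpha < 1,
            all(c_grid > 0))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Remove subjects from a cohort
#'
#' Applies an exclusion list uniformly to the feature tables, the
#' connectivity matrices and the clinical table, so every downstream stage
#' sees the same subject set.
#'
#' @param cohort a `synthetic_cohort` (or [read_cohort()] output)
#' @param exclude character vector of subject ids
#' @return the filtered cohort
#' @export
subject_exclusion <- function(cohort, exclude) {
  if (length(exclude) == 0L) return(cohort)
  unknown <- setdiff(exclude, cohort$subjects)
  if (length(unknown))
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  keep <- !(cohort$subjects %in% exclude)
  grp <- cohort$groups[keep]
  if (!all(c("patient", "control") %in% as.character(grp)))
    stop("exclusions would empty a group", call. = FALSE)
  cohort$tables <- lapply(cohort$tables, function(tab)
    regional_table(tab$values[keep, , drop = FALSE], tab$metric,
                   tab$groups[keep]))
  if (!is.null(cohort$fc)) cohort$fc <- cohort$fc[keep]
  if (!is.null(cohort$timeseries))
    cohort$timeseries <- cohort$timeseries[keep]
  cohort$clinical <- cohort$clinical[keep, , drop = FALSE]
  cohort$subjects <- cohort$subjects[keep]
  cohort$groups <- droplevels(grp)
  cohort$groups <- factor(as.character(cohort$groups),
                          levels = c("patient", "control"))
  cohort
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load) the cohort, apply exclusions, per-metric
#' region statistics + demographics + clinical correlation with Q-Q
#' screening, the extended-NBS threshold sweep, per-region nested-LOOCV
#' classification, and a final ranking. All tabular outputs are written
#' under `config$out_dir`, together with a run manifest (config echo,
#' derived stage seeds, file checksums).
#'
#' @param config a [pipeline_config()]
#' @param cohort optionally, a pre-built cohort (skips simulation)
#' @return list with `cohort`, `stats`, `demographics`, `correlation`,
#'   `nbs` (sweep list), `reports`, `ranking`, `manifest`
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  write_cohort(cohort, file.path(config$out_dir, "cohort"))
  cohort <- subject_exclusion(cohort, config$manual_exclusions)

  stats_list <- NULL
  demographics <- NULL
  correlation <- NULL
  if (isTRUE(config$stages[["stats"]])) {
    stats_list <- lapply(cohort$tables, region_stats,
                         alpha = config$alpha_discovery)
    stats_df <- do.call(rbind, lapply(names(stats_list), function(m) {
      df <- stats_list[[m]]
      cbind(metric = m, df)
    }))
    write.table(stats_df, file.path(config$out_dir, "region_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    demographics <- demographic_tests(cohort$clinical)

    sig_pairs <- do.call(rbind, lapply(names(stats_list), function(m) {
      sel <- select_significant(stats_list[[m]], config$alpha_discovery)
      if (length(sel) == 0L) return(NULL)
      data.frame(metric = m, region = sel, stringsAsFactors = FALSE)
    }))
    if (!is.null(sig_pairs) && nrow(sig_pairs) > 0L) {
      pat <- cohort$clinical$group == "patient"
      screen <- qq_outlier_screen(cohort$clinical$umsars_total[pat],
                                  ids = cohort$clinical$subject_id[pat],
                                  k = config$outlier_k)
      correlation <- clinical_correlation(cohort$tables, cohort$clinical,
                                          sig_pairs,
                                          exclude = screen$flagged,
                                          alpha = config$corr_alpha)
      write.table(correlation,
                  file.path(config$out_dir, "clinical_correlation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  nbs_sweep <- NULL
  if (isTRUE(config$stages[["nbs"]])) {
    nbs_sweep <- nbs_threshold_sweep(cohort$fc, cohort$groups,
                                     thresholds = config$nbs_thresholds,
                                     n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, "nbs"),
                                     alpha = config$nbs_alpha)
    jsonlite::write_json(lapply(nbs_sweep, nbs_result_json),
                         file.path(config$out_dir, "nbs_sweep.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  reports <- NULL
  ranking <- NULL
  if (isTRUE(config$stages[["classify"]])) {
    if (is.null(stats_list))
      stop("classify requires the stats stage; enable stages['stats']",
           call. = FALSE)
    nbs_feat <- NULL
    if (!is.null(nbs_sweep)) {
      k <- which(abs(config$nbs_thresholds -
                     config$nbs_feature_threshold) < 1e-12)
      if (length(k) == 1L) nbs_feat <- nbs_sweep[[k]]
    }
    reports <- list()
    for (r in seq_len(config$cohort$n_regions)) {
      fs <- assemble_features(r, stats_list, nbs_feat, cohort$tables,
                              cohort$fc,
                              alpha_feature = config$alpha_feature)
      if (fs$unclassifiable) next
      reports[[length(reports) + 1L]] <-
        nested_loocv_svm(fs, c_grid = config$c_grid)
    }
    if (length(reports) > 0L) {
      ranking <- rank_regions(reports, cutoff = config$accuracy_cutoff)
      write.table(ranking, file.path(config$out_dir, "region_ranking.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- write_manifest(config, cohort)
  list(cohort = cohort, stats = stats_list, demographics = demographics,
       correlation = correlation, nbs = nbs_sweep, reports = reports,
       ranking = ranking, manifest = manifest)
}

nbs_result_json <- function(res) {
  list(threshold = res$threshold, n_perm = res$n_perm, seed = res$seed,
       alpha = res$alpha,
       components = lapply(res$components, function(cc)
         list(nodes = cc$nodes, node_labels = cc$node_labels,
              size = cc$size, emp_p = cc$emp_p,
              significant = cc$significant,
              edges = cc$edges)),
       null_max_size = res$null_max_size)
}

write_manifest <- function(config, cohort) {
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  sums <- tools::md5sum(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("msanet")),
    seed = config$seed,
    stage_seeds = list(
      regional_tables = derive_seed(config$seed, "regional_tables"),
      fc_data = derive_seed(config$seed, "fc_data"),
      clinical = derive_seed(config$seed, "clinical"),
      nbs = derive_seed(config$seed, "nbs")),
    parameters = list(
      alpha_discovery = config$alpha_discovery,
      alpha_feature = config$alpha_feature,
      corr_alpha = config$corr_alpha,
      outlier_k = config$outlier_k,
      manual_exclusions = config$manual_exclusions,
      nbs_thresholds = config$nbs_thresholds,
      n_perm = config$n_perm,
      nbs_alpha = config$nbs_alpha,
      nbs_feature_threshold = config$nbs_feature_threshold,
      c_grid = config$c_grid,
      accuracy_cutoff = config$accuracy_cutoff),
    n_subjects = length(cohort$subjects),
    spec_digest = cohort$log$spec_digest,
    checksums = as.list(stats::setNames(unname(sums),
                                        basename(names(sums)))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
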