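#!/usr/bin/env Rscript
# Per-region multimodal classification. Each region's feature vector is
# its significant metrics (FDR p < 0.05) plus the significant-component
# edges incident to it at the 0.0010 threshold; a linear SVM is evaluated
# by nested leave-one-out cross-validation over the standard C grid and
# regions are ranked by accuracy.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

cohort <- read_cohort(cohort_dir)
stats_list <- lapply(cohort$tables, region_stats,
                     alpha = config$alpha_discovery)

sweep_json <- jsonlite::fromJSON(file.path(results_dir, "nbs_sweep.json"),
                                 simplifyVector = FALSE)
# rebuild the feature-threshold result in object form
sweep <- suppressWarnings(
  nbs_threshold_sweep(cohort$fc, cohort$groups,
                      thresholds = config$nbs_feature_threshold,
                      n_perm = config$n_perm,
                      seed = derive_seed(seed, "nbs"),
                      alpha = config$nbs_alpha))
nbs_feat <- sweep[[1]]

reports <- list()
for (r in seq_len(ncol(cohort$tables$GMV$values))) {
  fs <- assemble_features(r, stats_list, nbs_feat, cohort$tables,
                          cohort$fc, alpha_feature = config$alpha_feature)
  if (fs$unclassifiable) next
  reports[[length(reports) + 1L]] <- nested_loocv_svm(fs)
}
cat(sprintf("%d of %d regions carried at least one feature\n",
            length(reports), ncol(cohort$tables$GMV$values)))

ranking <- rank_regions(reports, cutoff = config$accuracy_cutoff)
write.table(ranking, file.path(results_dir, "region_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

top <- attr(ranking, "top")
cat(sprintf("%d region(s) above %.2f accuracy; leaders:\n",
            nrow(top), config$accuracy_cutoff))
print(head(ranking[, c("label", "features", "auc", "accuracy",
                       "sensitivity", "specificity")], 5),
      row.names = FALSE)
cat("wrote", file.path(results_dir, "region_ranking.tsv"), "\n")
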