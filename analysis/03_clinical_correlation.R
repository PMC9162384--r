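#!/usr/bin/env Rscript
# Correlate the significant imaging features with UMSARS-total among
# patients, after Q-Q outlier screening of the clinical scores. Features
# whose raw correlation p < 0.001 are selected.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

cohort <- read_cohort(cohort_dir)
stats_df <- read.delim(file.path(results_dir, "region_stats.tsv"))
sig_pairs <- stats_df[stats_df$significant, c("metric", "region")]

pat <- cohort$clinical$group == "patient"
screen <- qq_outlier_screen(cohort$clinical$umsars_total[pat],
                            ids = cohort$clinical$subject_id[pat],
                            k = config$outlier_k)
if (length(screen$flagged))
  cat("excluded as outliers:", paste(screen$flagged, collapse = ", "), "\n")

corr <- clinical_correlation(cohort$tables, cohort$clinical, sig_pairs,
                             exclude = screen$flagged,
                             alpha = config$corr_alpha)
write.table(corr, file.path(results_dir, "clinical_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- corr[corr$selected, ]
cat(sprintf("%d of %d feature(s) selected at raw p < %g\n",
            nrow(sel), nrow(corr), config$corr_alpha))
for (k in seq_len(nrow(sel)))
  cat(sprintf("  %s at %s: r = %+.3f (p = %.2g, n = %d)\n",
              sel$metric[k], sel$label[k], sel$r[k], sel$p[k], sel$n[k]))
cat("wrote", file.path(results_dir, "clinical_correlation.tsv"), "\n")
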