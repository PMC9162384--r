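#!/usr/bin/env Rscript
# Extended network-based statistics on the functional connectivity
# networks: edgewise pooled t-tests, p-thresholded binary difference
# networks, connected components, and a 5,000-permutation null of the
# maximal component size, swept over thresholds 0.0001..0.0010.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

cohort <- read_cohort(cohort_dir)

sweep <- suppressWarnings(
  nbs_threshold_sweep(cohort$fc, cohort$groups,
                      thresholds = config$nbs_thresholds,
                      n_perm = config$n_perm,
                      seed = derive_seed(seed, "nbs"),
                      alpha = config$nbs_alpha))
jsonlite::write_json(lapply(sweep, msanet:::nbs_result_json),
                     file.path(results_dir, "nbs_sweep.json"),
                     auto_unbox = TRUE, digits = NA)

for (res in sweep) {
  sig <- Filter(function(cc) cc$significant, res$components)
  cat(sprintf("threshold %.4f: %d component(s), %d significant\n",
              res$threshold, length(res$components), length(sig)))
  for (cc in sig) {
    incr <- sum(cc$edges$sign > 0); decr <- sum(cc$edges$sign < 0)
    cat(sprintf("  size %d (%s): emp p = %.4f, %d increased / %d decreased edge(s)\n",
                cc$size, paste(cc$node_labels, collapse = ","),
                cc$emp_p, incr, decr))
  }
}
cat("wrote", file.path(results_dir, "nbs_sweep.json"), "\n")
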