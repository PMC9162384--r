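#!/usr/bin/env Rscript
# Simulate the synthetic study cohort and write it as plain-text tables.
#
# The cohort emulates an MSA-c vs healthy-control imaging study: regional
# grey/white matter weighted volumes, FA, MD and fiber counts over a
# 116-region parcellation; per-subject Pearson connectivity matrices from
# simulated ROI time series; and a clinical table whose UMSARS scores are
# negatively correlated with chosen cerebellar microstructure features.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_config.R"))

cohort <- generate_cohort(spec)
write_cohort(cohort, cohort_dir)

cat(sprintf("cohort: %d patients, %d controls, %d regions (seed %d)\n",
            sum(cohort$groups == "patient"),
            sum(cohort$groups == "control"),
            ncol(cohort$tables$GMV$values), seed))
cat(sprintf("metrics: %s\n", paste(names(cohort$tables), collapse = ", ")))
pat <- cohort$clinical$group == "patient"
cat(sprintf("patient UMSARS-I %.2f +- %.2f, UMSARS-II %.2f +- %.2f\n",
            mean(cohort$clinical$umsars1[pat]), sd(cohort$clinical$umsars1[pat]),
            mean(cohort$clinical$umsars2[pat]), sd(cohort$clinical$umsars2[pat])))
cat("wrote", cohort_dir, "\n")
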