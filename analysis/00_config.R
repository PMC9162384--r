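# Shared settings for the numbered analysis drivers. Each driver can be
# run on its own (later ones read the outputs of earlier ones from
# `results/`). One master seed determines every stage.

library(msanet)

seed <- 20230901L
results_dir <- "results"
cohort_dir <- file.path(results_dir, "cohort")
dir.create(results_dir, showWarnings = FALSE)

# Study-scale defaults: 29 patients / 27 controls, 116 regions, planted
# cerebellar deficits, two planted connectivity components, UMSARS
# negatively tied to cerebellar microstructure.
spec <- cohort_spec(seed = seed)

config <- pipeline_config(out_dir = results_dir, seed = seed,
                          cohort = spec)
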