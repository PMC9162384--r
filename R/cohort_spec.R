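#' @rdname cohort_spec
#' @export
METRICS <- c("GMV", "WMV", "FA", "MD", "FIBER_COUNT")

#' Specify a synthetic two-group multimodal cohort
#'
#' A `cohort_spec` captures everything needed to simulate a patient/control
#' imaging cohort: group sizes, the parcellation size, per-metric baseline
#' distributions, planted group effects, the functional-connectivity model,
#' and the clinical-score model. Generation from a spec is fully determined
#' by `seed`.
#'
#' Defaults emulate an MSA-c vs healthy-control study: 29 patients and 27
#' controls over a 116-region (AAL-style) parcellation, with cerebellar
#' regions (indices 91-116 by convention here) carrying decreased grey/white
#' matter weighted volume, decreased fractional anisotropy and fiber counts,
#' increased mean diffusivity, a planted set of shifted functional edges
#' linking cerebellar and cerebral nodes, and UMSARS scores negatively
#' correlated with selected microstructure features.
#'
#' @param n_patients,n_controls group sizes (each >= 2)
#' @param n_regions number of atlas regions (>= 2)
#' @param region_labels optional character vector of length `n_regions`
#' @param metric_specs named list; each element `c(mean =, sd =)` with sd > 0
#' @param effects list of [effect_spec()] objects
#' @param fc_spec an [fc_spec()] object
#' @param clinical_spec a [clinical_spec()] object
#' @param seed master seed (expanded into per-stage child seeds, see
#'   [derive_seed()])
#' @return a validated list of class `cohort_spec`
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 29L,
                        n_controls = 27L,
                        n_regions = 116L,
                        region_labels = NULL,
                        metric_specs = default_metric_specs(),
                        effects = default_effects(),
                        fc_spec = msanet::fc_spec(),
                        clinical_spec = msanet::clinical_spec(),
                        seed = 1L) {
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(n_regions))
  spec <- structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions),
    region_labels = region_labels,
    metric_specs = metric_specs,
    effects = effects,
    fc_spec = fc_spec,
    clinical_spec = clinical_spec,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_metric_specs <- function() {
  list(GMV = c(mean = 0.45, sd = 0.05),
       WMV = c(mean = 0.30, sd = 0.04),
       FA = c(mean = 0.45, sd = 0.04),
       MD = c(mean = 8e-4, sd = 5e-5),
       FIBER_COUNT = c(mean = 500, sd = 80))
}

#' @rdname cohort_spec
#' @export
default_effects <- function() {
  # Cerebellar block = regions 91:116 by convention. Patterns mirror the
  # study design: volume loss across the cerebellum, focal WMV changes
  # (including one increased cerebral region), microstructural FA decrease /
  # MD increase extending to two cerebral regions, reduced fiber counts.
  list(effect_spec("GMV", 91:116, -2.0),
       effect_spec("WMV", c(95L, 96L, 113L, 114L), -1.5),
       effect_spec("WMV", 48L, 1.2),
       effect_spec("FA", 99:110, -1.5),
       effect_spec("MD", c(99:110, 55L, 2L), 1.5),
       effect_spec("FIBER_COUNT", c(95L, 96L, 99:108), -1.5))
}

#' Planted group effect on one regional metric
#'
#' @param metric one of `METRICS`
#' @param regions integer region indices carrying the effect
#' @param effect_size standardized mean difference (Cohen's d); negative
#'   means lower values in patients
#' @export
effect_spec <- function(metric, regions, effect_size) {
  metric <- match.arg(metric, METRICS)
  stopifnot(length(effect_size) == 1L, is.finite(effect_size))
  structure(list(metric = metric, regions = as.integer(regions),
                 effect_size = as.numeric(effect_size)),
            class = "effect_spec")
}

#' Functional-connectivity simulation model
#'
#' Subject time series are sampled from a multivariate normal whose
#' correlation matrix has `base_correlation` off the diagonal; in patients
#' the listed edges are shifted by `delta_r`. Connectivity matrices are then
#' computed from the time series by Pearson correlation, exactly as for
#' real data.
#'
#' @param series_length number of time points T (>= 8)
#' @param base_correlation common off-diagonal population correlation
#' @param planted_edges list of `list(i =, j =, delta_r =)` edge shifts
#'   applied to the patient group
#' @export
fc_spec <- function(series_length = 170L,
                    base_correlation = 0.1,
                    planted_edges = default_planted_edges()) {
  structure(list(series_length = as.integer(series_length),
                 base_correlation = as.numeric(base_correlation),
                 planted_edges = planted_edges),
            class = "fc_spec")
}

#' @rdname fc_spec
#' @export
planted_edge <- function(i, j, delta_r) {
  stopifnot(i != j, is.finite(delta_r))
  list(i = as.integer(min(i, j)), j = as.integer(max(i, j)),
       delta_r = as.numeric(delta_r))
}

#' @rdname fc_spec
#' @export
default_planted_edges <- function() {
  # Two components in the difference network, mixing increased and
  # decreased connectivity between cerebellar (91+) and cerebral nodes.
  list(planted_edge(7, 91, -0.3),
       planted_edge(7, 92, -0.3),
       planted_edge(61, 93, -0.3),
       planted_edge(79, 93, 0.3),
       planted_edge(80, 93, 0.3),
       planted_edge(25, 103, 0.3),
       planted_edge(25, 104, 0.3),
       planted_edge(31, 103, 0.3))
}

#' Clinical-score simulation model
#'
#' UMSARS-total is constructed with exact target population correlations
#' against chosen realized imaging features via the linear blend
#' `score = sum(rho_k * z_k) + sqrt(1 - sum(rho_k^2)) * noise`, then split
#' into UMSARS-I and UMSARS-II so that their sum reproduces the total
#' exactly. Controls carry no UMSARS scores.
#'
#' @param umsars1_mean,umsars1_sd,umsars2_mean,umsars2_sd UMSARS part
#'   means/SDs among patients
#' @param umsars12_cor assumed correlation between parts I and II (sets the
#'   implied total SD)
#' @param target_correlations list of `list(metric =, region =, rho =)`
#'   population correlations between a feature and UMSARS-total
#' @param age_patient_mean,age_patient_sd,age_control_mean,age_control_sd
#'   per-group age model
#' @param male_prop_patients,male_prop_controls male proportions; realized
#'   counts are `round(prop * n)` so the cohort gender table is fixed
#' @param duration_mean,duration_sd,moca_mean,moca_sd,hama_mean,hama_sd,
#'   hamd_mean,hamd_sd patient-only clinical scales
#' @export
clinical_spec <- function(umsars1_mean = 17.34, umsars1_sd = 5.65,
                          umsars2_mean = 17.07, umsars2_sd = 5.66,
                          umsars12_cor = 0.6,
                          target_correlations = default_target_correlations(),
                          age_patient_mean = 57.62, age_patient_sd = 6.00,
                          age_control_mean = 57.37, age_control_sd = 5.64,
                          male_prop_patients = 18 / 29,
                          male_prop_controls = 11 / 27,
                          duration_mean = 2.34, duration_sd = 1.49,
                          moca_mean = 24.17, moca_sd = 3.76,
                          hama_mean = 13.33, hama_sd = 6.43,
                          hamd_mean = 13.94, hamd_sd = 8.61) {
  structure(as.list(environment()), class = "clinical_spec")
}

#' @rdname clinical_spec
#' @export
target_correlation <- function(metric, region, rho) {
  metric <- match.arg(metric, METRICS)
  stopifnot(abs(rho) < 1)
  list(metric = metric, region = as.integer(region), rho = as.numeric(rho))
}

#' @rdname clinical_spec
#' @export
default_target_correlations <- function() {
  # FA at two cerebellar regions and the fiber count at one, negatively
  # related to clinical severity; sum of rho^2 must stay below 1.
  list(target_correlation("FA", 107, -0.5),
       target_correlation("FA", 108, -0.5),
       target_correlation("FIBER_COUNT", 96, -0.45))
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  if (spec$n_controls < 2L) stop("n_controls must be >= 2", call. = FALSE)
  if (spec$n_regions < 2L) stop("n_regions must be >= 2", call. = FALSE)
  if (length(spec$region_labels) != spec$n_regions)
    stop("region_labels must have length n_regions", call. = FALSE)
  if (anyDuplicated(spec$region_labels))
    stop("region_labels must be unique", call. = FALSE)
  for (m in names(spec$metric_specs)) {
    ms <- spec$metric_specs[[m]]
    if (!all(c("mean", "sd") %in% names(ms)) || !is.finite(ms["sd"]) ||
        ms["sd"] <= 0)
      stop("metric_specs[[", m, "]]: sd must be > 0", call. = FALSE)
  }
  for (ef in spec$effects) {
    if (!ef$metric %in% names(spec$metric_specs))
      stop("effects: unknown metric ", ef$metric, call. = FALSE)
    if (any(ef$regions < 1L) || any(ef$regions > spec$n_regions))
      stop("effects: regions out of range for metric ", ef$metric,
           call. = FALSE)
  }
  fs <- spec$fc_spec
  if (fs$series_length < 8L)
    stop("fc_spec: series_length must be >= 8", call. = FALSE)
  if (abs(fs$base_correlation) >= 1)
    stop("fc_spec: base_correlation must lie in (-1, 1)", call. = FALSE)
  for (e in fs$planted_edges) {
    if (e$i < 1L || e$j > spec$n_regions)
      stop("fc_spec: planted edge (", e$i, ",", e$j, ") out of range",
           call. = FALSE)
    if (abs(fs$base_correlation + e$delta_r) >= 1)
      stop("fc_spec: |base_correlation + delta_r| must be < 1 for edge (",
           e$i, ",", e$j, ")", call. = FALSE)
  }
  cs <- spec$clinical_spec
  for (f in c("umsars1_sd", "umsars2_sd", "age_patient_sd", "age_control_sd",
              "duration_sd", "moca_sd", "hama_sd", "hamd_sd")) {
    if (cs[[f]] <= 0) stop("clinical_spec: ", f, " must be > 0",
                           call. = FALSE)
  }
  rho2 <- sum(vapply(cs$target_correlations, function(t) t$rho^2, 0))
  if (rho2 >= 1)
    stop("clinical_spec: sum of squared target correlations must be < 1",
         call. = FALSE)
  for (t in cs$target_correlations) {
    if (abs(t$rho) >= 1)
      stop("clinical_spec: |rho| must be < 1", call. = FALSE)
    if (t$region < 1L || t$region > spec$n_regions)
      stop("clinical_spec: target region ", t$region, " out of range",
           call. = FALSE)
  }
  invisible(spec)
}
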