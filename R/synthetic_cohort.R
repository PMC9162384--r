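#' Generate a complete synthetic cohort
#'
#' Runs the three generation stages (regional tables, functional
#' connectivity, clinical scores) with per-stage child seeds derived from
#' `spec$seed`, so a cohort regenerates bit-identically from the same spec
#' and seed.
#'
#' @param spec a [cohort_spec()]
#' @param keep_timeseries keep the simulated ROI time series (memory-heavy
#'   for large cohorts)
#' @return a list of class `synthetic_cohort` with elements `tables` (one
#'   [regional_table] per metric), `fc` (per-subject connectivity matrices),
#'   `timeseries` (optional), `clinical`, `subjects`, `groups`, and `log`
#'   (seed and a spec digest)
#' @export
generate_cohort <- function(spec, keep_timeseries = FALSE) {
  validate_cohort_spec(spec)
  tables <- generate_regional_tables(spec)
  fcdat <- generate_fc_data(spec)
  clinical <- generate_clinical(spec, tables)
  cohort <- structure(list(
    tables = tables,
    fc = fcdat$fc,
    timeseries = if (keep_timeseries) fcdat$timeseries else NULL,
    clinical = clinical,
    subjects = fcdat$subjects,
    groups = fcdat$groups,
    log = list(seed = spec$seed, spec_digest = spec_digest(spec))
  ), class = "synthetic_cohort")
  cohort
}

subject_ids <- function(spec) {
  c(sprintf("P%02d", seq_len(spec$n_patients)),
    sprintf("C%02d", seq_len(spec$n_controls)))
}

group_factor <- function(spec) {
  factor(rep(c("patient", "control"), c(spec$n_patients, spec$n_controls)),
         levels = c("patient", "control"))
}

#' Simulate regional feature tables for every metric
#'
#' Each metric is drawn per region from independent Gaussians at the
#' metric's baseline mean/SD; planted effects shift the patient group by
#' `effect_size * sd` in the designated regions. FA is clipped to [0, 1],
#' MD floored at 0, and fiber counts are rounded to non-negative integers.
#'
#' @inheritParams generate_cohort
#' @return named list of [regional_table] objects, one per metric
#' @export
generate_regional_tables <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, "regional_tables"))
  n <- spec$n_patients + spec$n_controls
  ids <- subject_ids(spec)
  grp <- group_factor(spec)
  out <- list()
  for (m in names(spec$metric_specs)) {
    ms <- spec$metric_specs[[m]]
    vals <- matrix(rnorm(n * spec$n_regions, ms["mean"], ms["sd"]),
                   nrow = n, ncol = spec$n_regions,
                   dimnames = list(ids, spec$region_labels))
    for (ef in spec$effects) {
      if (ef$metric == m)
        vals[seq_len(spec$n_patients), ef$regions] <-
          vals[seq_len(spec$n_patients), ef$regions] +
          ef$effect_size * ms["sd"]
    }
    if (m == "FA") vals <- pmin(pmax(vals, 0), 1)
    if (m == "MD") vals <- pmax(vals, 0)
    if (m == "FIBER_COUNT") vals <- pmax(round(vals), 0)
    out[[m]] <- regional_table(vals, metric = m, groups = grp)
  }
  out
}

#' Regional feature table (subjects x regions, one metric)
#'
#' @param values numeric matrix, rows = subjects (rownames = ids), columns
#'   = region labels
#' @param metric metric identifier
#' @param groups factor with levels `patient`, `control`, one per row
#' @export
regional_table <- function(values, metric, groups) {
  stopifnot(is.matrix(values), nrow(values) == length(groups))
  groups <- factor(groups, levels = c("patient", "control"))
  if (any(is.na(groups))) stop("groups must be 'patient' or 'control'")
  structure(list(metric = metric, values = values,
                 subjects = rownames(values), groups = groups),
            class = "regional_table")
}

#' @export
print.regional_table <- function(x, ...) {
  cat(sprintf("<regional_table> %s: %d subjects (%d patients / %d controls) x %d regions\n",
              x$metric, nrow(x$values), sum(x$groups == "patient"),
              sum(x$groups == "control"), ncol(x$values)))
  invisible(x)
}

#' Simulate subject functional-connectivity matrices
#'
#' Builds the group population correlation matrices (a common
#' `base_correlation` off the diagonal; planted edges shifted by `delta_r`
#' in patients), samples T multivariate-normal time points per subject, and
#' computes each subject's Pearson connectivity matrix with [fc_matrix()] —
#' the same operation applied to real ROI time series.
#'
#' @inheritParams generate_cohort
#' @return list with `fc` (named list of symmetric unit-diagonal matrices),
#'   `timeseries` (named list of T x R matrices), `subjects`, `groups`
#' @export
generate_fc_data <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, "fc_data"))
  R <- spec$n_regions
  fs <- spec$fc_spec
  sigma_control <- matrix(fs$base_correlation, R, R)
  diag(sigma_control) <- 1
  sigma_patient <- sigma_control
  for (e in fs$planted_edges) {
    sigma_patient[e$i, e$j] <- sigma_patient[e$i, e$j] + e$delta_r
    sigma_patient[e$j, e$i] <- sigma_patient[e$i, e$j]
  }
  chol_c <- try(chol(sigma_control), silent = TRUE)
  chol_p <- try(chol(sigma_patient), silent = TRUE)
  if (inherits(chol_c, "try-error") || inherits(chol_p, "try-error"))
    stop("implied population covariance is not positive definite; ",
         "reduce |delta_r| or the planted-edge density", call. = FALSE)
  ids <- subject_ids(spec)
  grp <- group_factor(spec)
  ts_list <- vector("list", length(ids))
  fc_list <- vector("list", length(ids))
  names(ts_list) <- names(fc_list) <- ids
  for (s in seq_along(ids)) {
    ch <- if (grp[s] == "patient") chol_p else chol_c
    z <- matrix(rnorm(fs$series_length * R), fs$series_length, R)
    ts <- z %*% ch
    colnames(ts) <- spec$region_labels
    ts_list[[s]] <- ts
    fc_list[[s]] <- fc_matrix(ts)
  }
  list(fc = fc_list, timeseries = ts_list, subjects = ids, groups = grp)
}

#' Simulate the clinical table
#'
#' UMSARS-total is generated among patients with the requested population
#' correlations against realized imaging features: standardized feature
#' values are blended as `sum(rho_k * z_k) + sqrt(1 - sum(rho_k^2)) * eps`
#' (features at distinct regions are independent by construction, so each
#' pairwise target is attained). The total is then split into parts I and
#' II whose means/SDs follow the clinical spec and whose sum reproduces the
#' total exactly. Ages are Gaussian per group; gender counts are fixed at
#' `round(prop * n)` males per group.
#'
#' @inheritParams generate_cohort
#' @param tables output of [generate_regional_tables()] for the same spec
#'   (correlations are induced against the realized values)
#' @return a `data.frame` of class `clinical_table`
#' @export
generate_clinical <- function(spec, tables) {
  validate_cohort_spec(spec)
  set.seed(derive_seed(spec$seed, "clinical"))
  cs <- spec$clinical_spec
  n1 <- spec$n_patients
  n2 <- spec$n_controls
  grp <- group_factor(spec)
  ids <- subject_ids(spec)

  zsum <- rep(0, n1)
  for (t in cs$target_correlations) {
    tab <- tables[[t$metric]]
    if (is.null(tab))
      stop("target correlation refers to missing metric ", t$metric,
           call. = FALSE)
    if (t$region > ncol(tab$values))
      stop("target correlation region ", t$region,
           " not present in metric ", t$metric, call. = FALSE)
    x <- tab$values[tab$groups == "patient", t$region]
    zsum <- zsum + t$rho * as.vector(scale(x))
  }
  rho2 <- sum(vapply(cs$target_correlations, function(t) t$rho^2, 0))
  score <- zsum + sqrt(1 - rho2) * rnorm(n1)

  m_tot <- cs$umsars1_mean + cs$umsars2_mean
  sd_tot <- sqrt(cs$umsars1_sd^2 + cs$umsars2_sd^2 +
                 2 * cs$umsars12_cor * cs$umsars1_sd * cs$umsars2_sd)
  total <- m_tot + sd_tot * score
  frac <- cs$umsars1_sd / (cs$umsars1_sd + cs$umsars2_sd)
  split_sd <- sqrt(max(0, cs$umsars1_sd^2 - (frac * sd_tot)^2))
  u1 <- cs$umsars1_mean + frac * (total - m_tot) + rnorm(n1, 0, split_sd)
  u2 <- total - u1

  age <- c(rnorm(n1, cs$age_patient_mean, cs$age_patient_sd),
           rnorm(n2, cs$age_control_mean, cs$age_control_sd))
  n_male1 <- round(cs$male_prop_patients * n1)
  n_male2 <- round(cs$male_prop_controls * n2)
  gender <- c(sample(rep(c("M", "F"), c(n_male1, n1 - n_male1))),
              sample(rep(c("M", "F"), c(n_male2, n2 - n_male2))))

  clin <- data.frame(
    subject_id = ids,
    group = grp,
    age = age,
    gender = factor(gender, levels = c("M", "F")),
    umsars1 = c(u1, rep(NA_real_, n2)),
    umsars2 = c(u2, rep(NA_real_, n2)),
    umsars_total = c(total, rep(NA_real_, n2)),
    duration = c(pmax(rnorm(n1, cs$duration_mean, cs$duration_sd), 0.1),
                 rep(NA_real_, n2)),
    moca = c(pmin(pmax(rnorm(n1, cs$moca_mean, cs$moca_sd), 0), 30),
             rep(NA_real_, n2)),
    hama = c(pmax(rnorm(n1, cs$hama_mean, cs$hama_sd), 0),
             rep(NA_real_, n2)),
    hamd = c(pmax(rnorm(n1, cs$hamd_mean, cs$hamd_sd), 0),
             rep(NA_real_, n2)),
    stringsAsFactors = FALSE
  )
  class(clin) <- c("clinical_table", "data.frame")
  clin
}

# Deterministic polynomial digest of the serialized spec; recorded in the
# generation log so a cohort can be traced back to its spec.
spec_digest <- function(spec) {
  s <- jsonlite::toJSON(unclass_recursive(spec), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}
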