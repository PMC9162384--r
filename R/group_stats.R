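#' Region-wise two-sample t-tests
#'
#' Compares patients against controls in every region of a regional feature
#' table. The default is the pooled-variance Student t (positive t means
#' higher values in patients); Welch's correction is available as an
#' option. Regions with fewer than 2 non-missing values in either group are
#' excluded (NA statistics) with a warning.
#'
#' @param table a [regional_table]
#' @param welch use Welch's t instead of the pooled-variance Student t
#' @return data.frame with columns `region`, `label`, `n_patient`,
#'   `n_control`, `t`, `p`
#' @export
two_sample_t <- function(table, welch = FALSE) {
  stopifnot(inherits(table, "regional_table"))
  X <- table$values
  g1 <- table$groups == "patient"
  g2 <- table$groups == "control"
  R <- ncol(X)
  out <- data.frame(region = seq_len(R),
                    label = colnames(X),
                    n_patient = NA_integer_, n_control = NA_integer_,
                    t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  dropped <- integer(0)
  for (r in seq_len(R)) {
    x <- X[g1, r]; x <- x[!is.na(x)]
    y <- X[g2, r]; y <- y[!is.na(y)]
    out$n_patient[r] <- length(x)
    out$n_control[r] <- length(y)
    if (length(x) < 2L || length(y) < 2L) {
      dropped <- c(dropped, r)
      next
    }
    tt <- t.test(x, y, var.equal = !welch)
    out$t[r] <- unname(tt$statistic)
    out$p[r] <- tt$p.value
  }
  if (length(dropped))
    warning("regions excluded (fewer than 2 values in a group): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  attr(out, "metric") <- table$metric
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (monotone in rank, capped at 1, original order
#' preserved), delegating to [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in [0, 1]
#' @return adjusted p-values in the input order
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("p-values outside [0, 1] at positions: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Region-wise group statistics with FDR control
#'
#' Runs [two_sample_t()] and appends BH-adjusted p-values and a
#' significance flag at `alpha` (strict inequality). The FDR family is the
#' set of testable regions within this one metric.
#'
#' @inheritParams two_sample_t
#' @param alpha significance level on the adjusted p (default 0.001, the
#'   discovery threshold)
#' @return the [two_sample_t()] frame plus `p_fdr` and `significant`
#' @export
region_stats <- function(table, alpha = 0.001, welch = FALSE) {
  out <- two_sample_t(table, welch = welch)
  out$p_fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Select significant regions
#'
#' @param stats output of [region_stats()]
#' @param alpha level compared against the adjusted p (strict `<`)
#' @return integer vector of region indices
#' @export
select_significant <- function(stats, alpha = attr(stats, "alpha")) {
  if (is.null(alpha)) alpha <- 0.001
  stats$region[!is.na(stats$p_fdr) & stats$p_fdr < alpha]
}

#' Demographic matching tests
#'
#' Age is compared with a two-sided pooled-variance independent-samples
#' t-test; gender with Pearson's chi-square on the 2x2 group-by-gender
#' table (1 df, no continuity correction).
#'
#' @param clinical a clinical table ([generate_clinical()] layout) with
#'   `group`, `age`, `gender` columns
#' @return list with `age_p`, `gender_p`, `age_t`, `gender_chisq`,
#'   `gender_table`
#' @export
demographic_tests <- function(clinical) {
  stopifnot(all(c("group", "age", "gender") %in% names(clinical)))
  g <- factor(clinical$group, levels = c("patient", "control"))
  tt <- t.test(clinical$age[g == "patient"], clinical$age[g == "control"],
               var.equal = TRUE)
  tab <- table(g, factor(clinical$gender, levels = c("M", "F")))
  cs <- gender_test(tab)
  list(age_p = tt$p.value, gender_p = cs$p,
       age_t = unname(tt$statistic), gender_chisq = cs$statistic,
       gender_table = tab)
}

#' Pearson chi-square test on a 2x2 gender table
#'
#' No continuity correction (1 df). Errors if any row or column margin is
#' zero.
#'
#' @param tab 2x2 table of counts (groups x gender)
#' @return list with `statistic` and `p`
#' @export
gender_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("expected a 2x2 count table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the gender table is zero", call. = FALSE)
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(cs$statistic), p = cs$p.value)
}

#' Correlate imaging features with UMSARS-total
#'
#' Pearson correlation (two-sided test) between each selected (metric,
#' region) feature and patients' UMSARS-total, after removing excluded
#' subjects. The selection flag uses raw p < `alpha` (strict, uncorrected).
#'
#' @param tables named list of [regional_table] objects
#' @param clinical clinical table carrying `umsars_total`
#' @param pairs data.frame with columns `metric` and `region` naming the
#'   features to test (typically the significant discoveries)
#' @param exclude character vector of subject ids to drop (e.g. from
#'   [qq_outlier_screen()])
#' @param alpha selection level on the raw correlation p (default 0.001)
#' @return data.frame with `metric`, `region`, `label`, `r`, `p`, `n`,
#'   `selected`; excluded ids kept in the `excluded` attribute
#' @export
clinical_correlation <- function(tables, clinical, pairs,
                                 exclude = character(), alpha = 0.001) {
  stopifnot(all(c("metric", "region") %in% names(pairs)))
  pat <- clinical$group == "patient"
  scores <- clinical$umsars_total
  ids <- clinical$subject_id
  out <- data.frame(metric = character(0), region = integer(0),
                    label = character(0), r = numeric(0), p = numeric(0),
                    n = integer(0), selected = logical(0),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    m <- as.character(pairs$metric[k])
    r <- as.integer(pairs$region[k])
    tab <- tables[[m]]
    if (is.null(tab)) stop("no table for metric ", m, call. = FALSE)
    keep <- pat & !(ids %in% exclude) & !is.na(scores)
    keep_ids <- ids[keep]
    if (!all(keep_ids %in% tab$subjects))
      stop("clinical and feature tables disagree on subjects", call. = FALSE)
    x <- tab$values[match(keep_ids, tab$subjects), r]
    y <- scores[keep]
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      stop("fewer than 3 paired observations for ", m, " region ", r,
           call. = FALSE)
    if (sd(x) == 0)
      stop("zero-variance feature: ", m, " region ", r, call. = FALSE)
    ct <- cor.test(x, y, method = "pearson")
    out <- rbind(out, data.frame(
      metric = m, region = r, label = colnames(tab$values)[r],
      r = unname(ct$estimate), p = ct$p.value, n = length(x),
      selected = ct$p.value < alpha, stringsAsFactors = FALSE))
  }
  attr(out, "excluded") <- exclude
  out
}

#' Quantile-quantile outlier screening
#'
#' Emits normal Q-Q coordinates for plotting and applies an automatic
#' robust rule: subjects whose |(x - median) / (1.4826 MAD)| exceeds `k`
#' are flagged. A manual exclusion list is always honored on top of (or,
#' when MAD = 0 disables the automatic rule, instead of) the automatic
#' flags.
#'
#' @param x numeric values, one per subject (length >= 5)
#' @param ids subject identifiers (default names of `x`)
#' @param k robust z-score cutoff (default 3.5)
#' @param manual character vector of ids to exclude regardless of `x`
#' @return list with `qq` (data.frame `theoretical`, `sample`, `id`),
#'   `robust_z`, `flagged`
#' @export
qq_outlier_screen <- function(x, ids = names(x), k = 3.5,
                              manual = character()) {
  if (length(x) < 5L) stop("need at least 5 subjects", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  stopifnot(length(ids) == length(x))
  ord <- order(x)
  qq <- data.frame(theoretical = qnorm(ppoints(length(x))),
                   sample = x[ord], id = ids[ord],
                   stringsAsFactors = FALSE)
  md <- mad(x)
  if (md == 0) {
    warning("MAD is zero; automatic outlier rule disabled", call. = FALSE)
    z <- rep(NA_real_, length(x))
    flagged <- intersect(ids, manual)
  } else {
    z <- (x - median(x)) / md
    flagged <- union(ids[abs(z) > k], intersect(ids, manual))
  }
  names(z) <- ids
  list(qq = qq, robust_z = z, flagged = flagged)
}
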