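test_that("cohort regeneration is bit-identical under a fixed seed and differs across seeds", {
  spec <- tiny_spec(seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$tables, b$tables)
  expect_identical(a$fc, b$fc)
  expect_identical(a$clinical, b$clinical)
  spec2 <- tiny_spec(seed = 43)
  c2 <- generate_cohort(spec2)
  expect_false(identical(a$tables$GMV$values, c2$tables$GMV$values))
})

test_that("default spec reproduces the study group sizes", {
  spec <- cohort_spec(seed = 1)
  tabs <- generate_regional_tables(spec)
  expect_equal(sum(tabs$GMV$groups == "patient"), 29)
  expect_equal(sum(tabs$GMV$groups == "control"), 27)
  expect_equal(nrow(tabs$GMV$values), 56)
  expect_equal(ncol(tabs$GMV$values), 116)
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(tiny_spec(effects = list(effect_spec("GMV", 40, -1))),
               "regions out of range")
  ms <- default_metric_specs(); ms$FA["sd"] <- 0
  expect_error(cohort_spec(metric_specs = ms), "sd must be > 0")
  expect_error(tiny_spec(planted_edges = list(planted_edge(1, 2, 0.95))),
               "base_correlation \\+ delta_r")
})

test_that("planted effects shift patient means by d*sd and value constraints hold", {
  d <- -2
  spec <- tiny_spec(seed = 7, n_patients = 200, n_controls = 200,
                    effects = list(effect_spec("FA", 3:4, d),
                                   effect_spec("FIBER_COUNT", 5L, 1.5)))
  tabs <- generate_regional_tables(spec)
  fa <- tabs$FA
  shift <- mean(fa$values[fa$groups == "patient", 3]) -
    mean(fa$values[fa$groups == "control", 3])
  # sampling error of the mean difference at n = 200/200 is ~0.004
  expect_equal(shift, d * default_metric_specs()$FA["sd"],
               tolerance = 0.2, ignore_attr = TRUE)
  expect_true(all(fa$values >= 0 & fa$values <= 1))
  fib <- tabs$FIBER_COUNT$values
  expect_true(all(fib == round(fib) & fib >= 0))
})

test_that("a null spec gives calibrated region-wise false positives", {
  hits <- 0L; total <- 0L
  for (s in 1:60) {
    tabs <- generate_regional_tables(tiny_spec(seed = s, n_regions = 20,
                                               metrics = "GMV"))
    p <- two_sample_t(tabs$GMV)$p
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  rate <- hits / total
  # binomial 3-sigma band around the nominal 0.05
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / total))
})

test_that("connectivity matrices are symmetric, unit-diagonal and bounded", {
  spec <- tiny_spec(seed = 5, planted_edges = list(planted_edge(1, 2, 0.4)))
  fcd <- generate_fc_data(spec)
  for (m in fcd$fc[c(1, 10, 19)]) {
    expect_identical(m, t(m))
    expect_equal(unname(diag(m)), rep(1, ncol(m)))
    expect_true(all(m >= -1 & m <= 1))
  }
})

test_that("null FC data has small off-diagonal correlations at long T", {
  spec <- tiny_spec(seed = 11, n_regions = 10, series_length = 200,
                    base_correlation = 0)
  fcd <- generate_fc_data(spec)
  offdiag <- abs(do.call(rbind, lapply(fcd$fc, function(m) m[upper.tri(m)])))
  expect_gt(mean(offdiag < 0.2), 0.99)
})

test_that("planted FC edges attain the shifted population correlation", {
  spec <- tiny_spec(seed = 3, n_patients = 150, n_controls = 150,
                    n_regions = 8, series_length = 300,
                    base_correlation = 0.1,
                    planted_edges = list(planted_edge(1, 2, 0.5)))
  fcd <- generate_fc_data(spec)
  pat <- vapply(fcd$fc[fcd$groups == "patient"], function(m) m[1, 2], 0)
  con <- vapply(fcd$fc[fcd$groups == "control"], function(m) m[1, 2], 0)
  expect_equal(mean(pat), 0.6, tolerance = 0.05)
  expect_equal(mean(con), 0.1, tolerance = 0.05)
})

test_that("an over-planted covariance is rejected as not positive definite", {
  spec <- tiny_spec(n_regions = 6, base_correlation = -0.15,
                    planted_edges = list(planted_edge(1, 2, -0.8),
                                         planted_edge(1, 3, -0.8),
                                         planted_edge(2, 3, -0.8)))
  expect_error(generate_fc_data(spec), "positive definite")
})

test_that("UMSARS-total equals part I plus part II exactly, controls carry no scores", {
  co <- generate_cohort(tiny_spec(seed = 9))
  pat <- co$clinical$group == "patient"
  expect_equal(co$clinical$umsars1[pat] + co$clinical$umsars2[pat],
               co$clinical$umsars_total[pat])
  expect_true(all(is.na(co$clinical$umsars_total[!pat])))
  expect_true(all(is.na(co$clinical$umsars1[!pat])))
})

test_that("patient score means approach the study targets", {
  spec <- cohort_spec(n_patients = 600, n_controls = 20, seed = 4)
  tabs <- generate_regional_tables(spec)
  clin <- generate_clinical(spec, tabs)
  pat <- clin$group == "patient"
  expect_equal(mean(clin$umsars1[pat]), 17.34, tolerance = 0.05)
  expect_equal(mean(clin$umsars2[pat]), 17.07, tolerance = 0.05)
  expect_equal(sd(clin$umsars1[pat]), 5.65, tolerance = 0.12)
})

test_that("planted clinical correlation is realized in large samples", {
  spec <- cohort_spec(n_patients = 500, n_controls = 20, seed = 13,
                      n_regions = 12,
                      region_labels = sprintf("R%03d", 1:12),
                      effects = list(),
                      fc_spec = fc_spec(series_length = 60,
                                        planted_edges = list()),
                      clinical_spec = clinical_spec(
                        target_correlations =
                          list(target_correlation("FA", 3, -0.6))))
  tabs <- generate_regional_tables(spec)
  clin <- generate_clinical(spec, tabs)
  pat <- clin$group == "patient"
  r <- cor(tabs$FA$values[pat, 3], clin$umsars_total[pat])
  expect_gt(r, -0.68)
  expect_lt(r, -0.52)
})

test_that("clinical generation rejects targets missing from the tables", {
  spec <- tiny_spec(seed = 2)
  tabs <- generate_regional_tables(spec)
  spec$clinical_spec$target_correlations <-
    list(target_correlation("MD", 11, -0.4))
  tabs$MD <- NULL
  expect_error(generate_clinical(spec, tabs), "MD")
})

test_that("cohort directories round-trip through the text formats", {
  co <- generate_cohort(tiny_spec(seed = 21, n_regions = 6))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$tables$GMV$values, co$tables$GMV$values,
               tolerance = 1e-12)
  expect_identical(back$subjects, co$subjects)
  expect_identical(as.character(back$groups), as.character(co$groups))
  expect_equal(back$fc[[3]], co$fc[[3]], tolerance = 1e-12)
  expect_equal(back$clinical$umsars_total, co$clinical$umsars_total,
               tolerance = 1e-9)
})
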