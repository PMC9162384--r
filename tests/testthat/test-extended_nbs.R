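make_fc_set <- function(seed, n1 = 10, n2 = 9, R = 6, T = 40,
                        planted = list(), base = 0.1) {
  spec <- tiny_spec(seed = seed, n_regions = R, n_patients = n1,
                    n_controls = n2, series_length = T,
                    base_correlation = base, planted_edges = planted)
  generate_fc_data(spec)
}

test_that("edgewise statistics agree with stats::t.test on every edge", {
  fcd <- make_fc_set(1)
  dn <- edgewise_stats(fcd$fc, fcd$groups)
  pat <- which(fcd$groups == "patient")
  con <- which(fcd$groups == "control")
  for (e in list(c(1, 2), c(2, 5), c(3, 6))) {
    x <- vapply(fcd$fc[pat], function(m) m[e[1], e[2]], 0)
    y <- vapply(fcd$fc[con], function(m) m[e[1], e[2]], 0)
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(dn$t[e[1], e[2]], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(dn$p[e[1], e[2]], tt$p.value, tolerance = 1e-10)
  }
  expect_identical(dn$t, t(dn$t))
  expect_identical(dn$p, t(dn$p))
  # group swap negates every t
  swapped <- factor(ifelse(fcd$groups == "patient", "control", "patient"),
                    levels = c("patient", "control"))
  dn2 <- edgewise_stats(fcd$fc, swapped)
  expect_equal(dn2$t, -dn$t, tolerance = 1e-12)
})

test_that("identical group samples give a flat difference network", {
  fcd <- make_fc_set(2, n1 = 5, n2 = 5)
  fcs <- c(fcd$fc[1:5], fcd$fc[1:5])   # controls duplicate the patients
  names(fcs) <- sprintf("S%02d", 1:10)
  grp <- rep(c("patient", "control"), each = 5)
  dn <- edgewise_stats(fcs, grp)
  off <- upper.tri(dn$t)
  expect_true(all(abs(dn$t[off]) < 1e-12))
  expect_true(all(dn$p[off] == 1))
})

test_that("binarization applies a strict threshold and no self-loops", {
  fcd <- make_fc_set(3)
  dn <- edgewise_stats(fcd$fc, fcd$groups)
  dn$p[1, 2] <- dn$p[2, 1] <- 5e-5
  dn$p[3, 4] <- dn$p[4, 3] <- 1e-4    # exactly at the threshold
  adj <- nbs_binarize(dn, 1e-4)
  expect_true(adj[1, 2])
  expect_false(adj[3, 4])             # tie excluded
  expect_false(any(diag(adj)))
  expect_error(nbs_binarize(dn, 0), "threshold")
  expect_error(nbs_binarize(dn, 1), "threshold")
})

test_that("component extraction matches hand cases and ordering rules", {
  adj <- matrix(FALSE, 5, 5)
  adj[1, 2] <- adj[2, 1] <- TRUE
  adj[2, 3] <- adj[3, 2] <- TRUE
  comps <- nbs_components(adj)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$nodes, c(1L, 2L, 3L))
  expect_equal(comps[[1]]$size, 3L)
  expect_length(nbs_components(matrix(FALSE, 4, 4)), 0)
  # two equal-size components order by smallest node
  adj2 <- matrix(FALSE, 6, 6)
  adj2[5, 6] <- adj2[6, 5] <- TRUE
  adj2[1, 3] <- adj2[3, 1] <- TRUE
  comps2 <- nbs_components(adj2)
  expect_equal(comps2[[1]]$nodes, c(1L, 3L))
  expect_equal(comps2[[2]]$nodes, c(5L, 6L))
  # edge signs are annotation from the t matrix
  tm <- matrix(0, 5, 5); tm[1, 2] <- tm[2, 1] <- 2.5
  tm[2, 3] <- tm[3, 2] <- -3
  cc <- nbs_components(adj, tmat = tm)[[1]]
  expect_equal(cc$edges$sign, c(1, -1))
})

test_that("components equal breadth-first and igraph oracles on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:30) {
    n <- sample(2:9, 1)
    adj <- random_symmetric_adj(n, 0.3, seed = s)
    mine <- lapply(nbs_components(adj), `[[`, "nodes")
    expect_identical(mine, components_bruteforce(adj))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    ig <- split(seq_len(n), memb)
    ig <- Filter(function(nodes) sum(adj[nodes, nodes]) > 0, ig)
    ig <- unname(lapply(ig, as.integer))
    sizes <- lengths(ig); mins <- vapply(ig, min, 0L)
    expect_identical(mine, ig[order(-sizes, mins)])
  }
})

test_that("empirical p follows the printed permutation formula", {
  fcd <- make_fc_set(5, n1 = 8, n2 = 8, R = 5, T = 20)
  suppressWarnings(
    res <- nbs_permutation_test(fcd$fc, fcd$groups, threshold = 0.3,
                                n_perm = 50, seed = 9))
  expect_length(res$null_max_size, 50)
  for (cc in res$components) {
    expect_equal(cc$emp_p, sum(res$null_max_size > cc$size) / 50)
    expect_identical(cc$significant, cc$emp_p < 0.05)
  }
  # inclusive variant counts ties in the null
  suppressWarnings(
    res2 <- nbs_permutation_test(fcd$fc, fcd$groups, threshold = 0.3,
                                 n_perm = 50, seed = 9, inclusive = TRUE))
  for (k in seq_along(res2$components))
    expect_equal(res2$components[[k]]$emp_p,
                 sum(res2$null_max_size >= res2$components[[k]]$size) / 50)
  expect_warning(nbs_permutation_test(fcd$fc, fcd$groups, threshold = 0.3,
                                      n_perm = 20, seed = 1),
                 "resolution")
})

test_that("permutation results are bit-identical under a fixed seed", {
  fcd <- make_fc_set(6, R = 8)
  suppressWarnings({
    a <- nbs_permutation_test(fcd$fc, fcd$groups, 0.05, n_perm = 60,
                              seed = 12)
    b <- nbs_permutation_test(fcd$fc, fcd$groups, 0.05, n_perm = 60,
                              seed = 12)
    c2 <- nbs_permutation_test(fcd$fc, fcd$groups, 0.05, n_perm = 60,
                               seed = 13)
  })
  expect_identical(a, b)
  expect_false(identical(a$null_max_size, c2$null_max_size))
})

test_that("the sweep shares one permutation stream and nests edge sets", {
  fcd <- make_fc_set(7, R = 8, T = 30)
  suppressWarnings({
    sweep <- nbs_threshold_sweep(fcd$fc, fcd$groups,
                                 thresholds = c(0.01, 0.05, 0.2),
                                 n_perm = 40, seed = 4)
    single <- nbs_permutation_test(fcd$fc, fcd$groups, 0.05, n_perm = 40,
                                   seed = 4)
  })
  expect_length(sweep, 3)
  expect_identical(sweep[[2]]$null_max_size, single$null_max_size)
  expect_identical(lapply(sweep[[2]]$components, `[[`, "nodes"),
                   lapply(single$components, `[[`, "nodes"))
  # max component size is non-decreasing in the threshold
  maxsize <- vapply(sweep, function(r)
    if (length(r$components)) max(vapply(r$components, `[[`, 0L, "size"))
    else 0L, 0L)
  expect_true(all(diff(maxsize) >= 0))
  # every component at a lower threshold sits inside one at a higher
  for (cc in sweep[[1]]$components) {
    inside <- any(vapply(sweep[[3]]$components,
                         function(big) all(cc$nodes %in% big$nodes), TRUE))
    expect_true(inside)
  }
  expect_error(nbs_threshold_sweep(fcd$fc, fcd$groups,
                                   thresholds = c(0.05, 0.01), n_perm = 10),
               "increasing")
})

test_that("a planted edge dominates the difference network", {
  hits <- 0L
  for (s in 1:10) {
    fcd <- make_fc_set(800 + s, n1 = 29, n2 = 27, R = 10, T = 170,
                       planted = list(planted_edge(1, 2, 0.5)))
    dn <- edgewise_stats(fcd$fc, fcd$groups)
    pm <- dn$p; diag(pm) <- NA
    best <- which(pm == min(pm, na.rm = TRUE), arr.ind = TRUE)
    if (any(best[, 1] == 1 & best[, 2] == 2)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
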