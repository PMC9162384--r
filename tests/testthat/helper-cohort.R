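# Shared fixture builders; everything is generated in code at test time.

# Small cohort spec for fast tests. All planted structure is optional.
tiny_spec <- function(seed = 1, n_regions = 12, n_patients = 10,
                      n_controls = 9, effects = list(),
                      planted_edges = list(), series_length = 60,
                      base_correlation = 0.1,
                      target_correlations = list(),
                      metrics = NULL) {
  ms <- default_metric_specs()
  if (!is.null(metrics)) ms <- ms[metrics]
  cohort_spec(n_patients = n_patients, n_controls = n_controls,
              n_regions = n_regions,
              metric_specs = ms,
              effects = effects,
              fc_spec = fc_spec(series_length = series_length,
                                base_correlation = base_correlation,
                                planted_edges = planted_edges),
              clinical_spec = clinical_spec(
                target_correlations = target_correlations),
              seed = seed)
}

# Regional table straight from a matrix (bypasses the generator).
make_table <- function(values, metric = "GMV",
                       n_patients = ceiling(nrow(values) / 2)) {
  n <- nrow(values)
  ids <- c(sprintf("P%02d", seq_len(n_patients)),
           sprintf("C%02d", seq_len(n - n_patients)))
  rownames(values) <- ids
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("R%03d", seq_len(ncol(values)))
  regional_table(values, metric = metric,
                 groups = rep(c("patient", "control"),
                              c(n_patients, n - n_patients)))
}

# Feature set for classifier tests without running the whole pipeline.
make_feature_set <- function(X, n_patients = 29, region = 1L) {
  n <- nrow(X)
  ids <- c(sprintf("P%02d", seq_len(n_patients)),
           sprintf("C%02d", seq_len(n - n_patients)))
  dimnames(X) <- list(ids, paste0("f", seq_len(ncol(X))))
  structure(list(region = region, label = sprintf("R%03d", region),
                 feature_names = colnames(X), X = X,
                 groups = factor(rep(c("patient", "control"),
                                     c(n_patients, n - n_patients)),
                                 levels = c("patient", "control")),
                 subjects = ids, unclassifiable = FALSE),
            class = "region_feature_set")
}

# Independent brute-force Benjamini-Hochberg step-up (test oracle).
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (k in n:1) {
    i <- ord[k]
    val <- min(prev, p[i] * n / k)
    val <- min(val, 1)
    adj[i] <- val
    prev <- val
  }
  adj
}

# Independent component finder: repeated breadth-first search over an
# adjacency matrix (test oracle for the union-find implementation).
components_bruteforce <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    nodes <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nodes <- c(nodes, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (sum(adj[nodes, nodes, drop = FALSE]) > 0)   # needs >= 1 edge
      comps[[length(comps) + 1L]] <- sort(nodes)
  }
  sizes <- lengths(comps)
  mins <- vapply(comps, function(x) if (length(x)) min(x) else 0L, 0L)
  comps[order(-sizes, mins)]
}

random_symmetric_adj <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- runif(sum(ut)) < p_edge
  adj | t(adj)
}
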