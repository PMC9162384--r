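#' Edgewise group statistics on connectivity matrices
#'
#' For every unordered region pair (i < j), a two-sided pooled-variance t
#' test compares the edge's connectivity values between patients and
#' controls (positive t = stronger connectivity in patients). Results are
#' mirrored into symmetric t and p matrices — the "difference network"
#' whose edges carry p-values. Edges with zero variance in both groups get
#' t = 0, p = 1 with a warning.
#'
#' The edgewise t is computed in vectorized form over all R(R-1)/2 edges
#' (the permutation test below re-runs it thousands of times); it is
#' unit-tested against [stats::t.test()].
#'
#' @param fcs list of symmetric R x R connectivity matrices, one per
#'   subject, all sharing dimnames
#' @param groups factor (levels `patient`, `control`) aligned with `fcs`
#' @return list of class `difference_network`: `t`, `p` (R x R symmetric
#'   matrices), `labels`, `n_patient`, `n_control`
#' @export
edgewise_stats <- function(fcs, groups) {
  st <- fc_stack(fcs)
  groups <- factor(groups, levels = c("patient", "control"))
  stopifnot(length(groups) == nrow(st$X))
  i1 <- which(groups == "patient")
  i2 <- which(groups == "control")
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  res <- pooled_t_rows(st$X, i1, i2)
  if (any(res$zero_var))
    warning(sum(res$zero_var),
            " edge(s) with zero variance in both groups set to p = 1",
            call. = FALSE)
  R <- st$R
  tm <- matrix(0, R, R, dimnames = list(st$labels, st$labels))
  pm <- matrix(1, R, R, dimnames = list(st$labels, st$labels))
  tm[st$ut] <- res$t
  pm[st$ut] <- res$p
  tm <- tm + t(tm)
  pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
  diag(pm) <- 1
  structure(list(t = tm, p = pm, labels = st$labels,
                 n_patient = length(i1), n_control = length(i2)),
            class = "difference_network")
}

# Stack subject matrices into an n_subjects x n_edges matrix over the
# upper triangle (column-major order), with the edge index map.
fc_stack <- function(fcs) {
  stopifnot(length(fcs) >= 2L)
  R <- nrow(fcs[[1]])
  labels <- rownames(fcs[[1]])
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(R))
  ut <- which(upper.tri(fcs[[1]]))
  X <- matrix(NA_real_, nrow = length(fcs), ncol = length(ut))
  for (s in seq_along(fcs)) {
    m <- fcs[[s]]
    if (!identical(dim(m), c(R, R)))
      stop("all connectivity matrices must share the same shape",
           call. = FALSE)
    X[s, ] <- m[ut]
  }
  ij <- arrayInd(ut, c(R, R))
  list(X = X, ut = ut, edge_i = ij[, 1], edge_j = ij[, 2],
       R = R, labels = labels)
}

# Vectorized two-sided pooled-variance t over the columns of X for row
# index sets i1 (patients) and i2 (controls).
pooled_t_rows <- function(X, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  ss1 <- colSums(X[i1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(X[i2, , drop = FALSE]^2) - n2 * m2^2
  df <- n1 + n2 - 2
  sp <- sqrt(pmax(ss1 + ss2, 0) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- 2 * pt(-abs(t), df)
  list(t = t, p = p, zero_var = se == 0 & d == 0)
}

#' Threshold a difference network into a binary adjacency
#'
#' An edge is present iff its raw p-value is strictly below `threshold`
#' (ties at the threshold are excluded); the diagonal is never an edge.
#'
#' @param diff a `difference_network` from [edgewise_stats()]
#' @param threshold p-value threshold in (0, 1)
#' @return logical R x R symmetric adjacency matrix
#' @export
nbs_binarize <- function(diff, threshold) {
  stopifnot(inherits(diff, "difference_network"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  adj <- diff$p < threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  adj
}

#' Connected components of a binary difference network
#'
#' Maximal connected subgraphs with at least one edge (isolated nodes are
#' not components); component size is its number of regions. Components
#' are ordered by size descending, ties broken by smallest node index.
#' Edge signs (+1 increased in patients, -1 decreased) are annotation
#' taken from the t matrix; they play no role in component formation.
#'
#' @param adj logical symmetric adjacency (from [nbs_binarize()])
#' @param tmat optional t-statistic matrix supplying edge signs
#' @param labels optional region labels
#' @return list of components, each `list(nodes, size, edges)` where
#'   `edges` is a data.frame with `i`, `j`, `sign`, `t`
#' @export
nbs_components <- function(adj, tmat = NULL, labels = rownames(adj)) {
  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (nrow(ut) == 0L) return(list())
  comp_id <- uf_components(ut[, 1], ut[, 2], nrow(adj))
  edge_comp <- comp_id[ut[, 1]]
  comps <- list()
  for (cid in unique(edge_comp)) {
    e <- ut[edge_comp == cid, , drop = FALSE]
    nodes <- sort(unique(c(e[, 1], e[, 2])))
    tv <- if (!is.null(tmat)) tmat[e] else rep(NA_real_, nrow(e))
    edges <- data.frame(i = e[, 1], j = e[, 2],
                        sign = ifelse(is.na(tv), NA_real_, sign(tv)),
                        t = tv)
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    comps[[length(comps) + 1L]] <-
      list(nodes = nodes, size = length(nodes), edges = edges,
           node_labels = if (!is.null(labels)) labels[nodes] else NULL)
  }
  sizes <- vapply(comps, `[[`, 0L, "size")
  mins <- vapply(comps, function(cc) min(cc$nodes), 0L)
  comps[order(-sizes, mins)]
}

# Union-find with path compression; returns a component id per node.
uf_components <- function(ei, ej, n) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(ei)) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, 0L)
}

# Max component size given edge endpoint vectors (fast path for the
# permutation loop); 0 when the edge set is empty.
uf_max_size <- function(ei, ej, n) {
  if (length(ei) == 0L) return(0L)
  nodes <- unique(c(ei, ej))
  map <- integer(n)
  map[nodes] <- seq_along(nodes)
  cid <- uf_components(map[ei], map[ej], length(nodes))
  max(tabulate(cid))
}

#' Extended-NBS permutation test
#'
#' Runs the full extended network-based-statistics procedure at one
#' p-value threshold: edgewise pooled-t difference network, binarization
#' at the threshold, observed connected components, then `n_perm` label
#' permutations (group sizes preserved) through the identical
#' edgewise-binarize-components chain, keeping the maximal component size
#' of each permutation. Each observed component's empirical p-value is the
#' fraction of permutations whose maximal size STRICTLY exceeds that
#' component's size (count / n_perm; the observed labeling is not added to
#' the null). A component is significant when its empirical p < `alpha`.
#'
#' @inheritParams edgewise_stats
#' @param threshold edge p-value threshold in (0, 1)
#' @param n_perm number of permutations (default 5000)
#' @param seed RNG seed for the permutation stream
#' @param alpha component significance level (default 0.05)
#' @param plus_one use the (count + 1) / (n_perm + 1) estimator instead of
#'   the plain count / n_perm
#' @param inclusive count permutations whose maximal size is greater than
#'   OR EQUAL TO the observed component size (the classical
#'   network-based-statistics convention). The default strict `>` follows
#'   the procedure as published here, but note it is anticonservative for
#'   small components under sparse nulls: a lone significant edge (size 2)
#'   is beaten only by permutations reaching size 3, so its empirical p
#'   can be tiny even under the null. The inclusive variant restores the
#'   usual calibration.
#' @return list of class `nbs_result`: `threshold`, `components` (each
#'   with `emp_p` and `significant`), `null_max_size`, `n_perm`, `seed`,
#'   `alpha`, `diff` (the observed difference network)
#' @export
nbs_permutation_test <- function(fcs, groups, threshold, n_perm = 5000L,
                                 seed = 1L, alpha = 0.05,
                                 plus_one = FALSE, inclusive = FALSE) {
  res <- nbs_threshold_sweep(fcs, groups, thresholds = threshold,
                             n_perm = n_perm, seed = seed, alpha = alpha,
                             plus_one = plus_one, inclusive = inclusive)
  res[[1]]
}

#' Extended-NBS threshold sweep
#'
#' Repeats the permutation test over an increasing ladder of edge
#' thresholds (default 0.0001 to 0.001 in steps of 0.0001). The same
#' permutation label sequences (hence one shared null RNG stream) are
#' reused across thresholds: each permutation's edgewise p-values are
#' computed once and thresholded at every level.
#'
#' @inheritParams nbs_permutation_test
#' @param thresholds strictly increasing vector of thresholds in (0, 1)
#' @return list of `nbs_result`, one per threshold
#' @export
nbs_threshold_sweep <- function(fcs, groups,
                                thresholds = seq(1e-4, 1e-3, by = 1e-4),
                                n_perm = 5000L, seed = 1L, alpha = 0.05,
                                plus_one = FALSE, inclusive = FALSE) {
  thresholds <- as.numeric(thresholds)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (length(thresholds) > 1L && any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (n_perm < 20 / alpha)
    warning("n_perm = ", n_perm, " gives empirical p resolution coarser ",
            "than alpha/20; consider more permutations", call. = FALSE)

  st <- fc_stack(fcs)
  groups <- factor(groups, levels = c("patient", "control"))
  i1 <- which(groups == "patient")
  i2 <- which(groups == "control")
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  n <- nrow(st$X)
  n1 <- length(i1)

  diff <- edgewise_stats(fcs, groups)
  obs_p <- diff$p[st$ut]

  # one permutation stream shared by all thresholds
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  null_max <- matrix(0L, nrow = n_perm, ncol = length(thresholds))
  for (b in seq_len(n_perm)) {
    p1 <- perms[seq_len(n1), b]
    p2 <- perms[-seq_len(n1), b]
    pv <- pooled_t_rows(st$X, p1, p2)$p
    for (k in seq_along(thresholds)) {
      sel <- which(pv < thresholds[k])
      null_max[b, k] <- uf_max_size(st$edge_i[sel], st$edge_j[sel], st$R)
    }
  }

  out <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    adj <- matrix(FALSE, st$R, st$R)
    sel <- which(obs_p < thresholds[k])
    adj[st$ut[sel]] <- TRUE
    adj <- adj | t(adj)
    dimnames(adj) <- list(st$labels, st$labels)
    comps <- nbs_components(adj, tmat = diff$t, labels = st$labels)
    for (ci in seq_along(comps)) {
      exceed <- if (inclusive) sum(null_max[, k] >= comps[[ci]]$size)
                else sum(null_max[, k] > comps[[ci]]$size)
      emp <- if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
      comps[[ci]]$emp_p <- emp
      comps[[ci]]$significant <- emp < alpha
    }
    out[[k]] <- structure(list(threshold = thresholds[k],
                               components = comps,
                               null_max_size = null_max[, k],
                               n_perm = as.integer(n_perm),
                               seed = as.integer(seed),
                               alpha = alpha, diff = diff),
                          class = "nbs_result")
  }
  out
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> threshold %g, %d permutation(s), %d component(s)\n",
              x$threshold, x$n_perm, length(x$components)))
  for (cc in x$components)
    cat(sprintf("  size %d (nodes %s...): empirical p = %.4f%s\n",
                cc$size, paste(head(cc$nodes, 5), collapse = ","),
                cc$emp_p, if (cc$significant) " *" else ""))
  invisible(x)
}
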