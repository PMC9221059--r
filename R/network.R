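# Permutation-calibrated edge significance and network construction:
# null-model fitting with tail extrapolation, thresholding at very small
# p-values, optional data-processing-inequality pruning and top-k edge
# selection.

new_network <- function(nodes, edges, params = list()) {
  stopifnot(all(c("a", "b", "mi") %in% colnames(edges)))
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(nodes)), edges = edges,
                 params = params), class = "pcn_network")
}

#' @export
print.pcn_network <- function(x, ...) {
  cat(sprintf("pcn_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a network to an igraph object
#' @param net a `pcn_network`.
#' @param weighted attach MI as edge attribute `mi`.
#' @return an undirected simple `igraph` graph including isolated nodes.
#' @export
as_igraph <- function(net, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (weighted && nrow(net$edges))
    igraph::E(g)$mi <- net$edges$mi
  g
}

#' Calibrate the null distribution of mutual information
#'
#' Pools MI values from permuted protein pairs (one member of each random
#' pair is shuffled across samples, destroying any dependence) and fits
#' the tail law \eqn{\log_{10} p(MI \ge x) = a + b x} by least squares on
#' the upper `tail_frac` of the pooled values. The fitted line is
#' extrapolated to assign p-values far below the permutation floor (the
#' edge threshold of 1e-8 cannot be reached empirically at feasible
#' permutation counts).
#'
#' Pooled null MI values are kept (as unique values with their empirical
#' survival) so that p-values in the empirically measurable range come
#' straight from the permutation distribution; the fitted line is used
#' only below the resolution floor of `min_tail_count` pool exceedances.
#'
#' @param ranked matrix from [copula_rank_transform()].
#' @param n_perm number of permuted pairs to pool (>= 1e5 recommended).
#' @param seed RNG seed.
#' @param tail_frac fraction of the pool used for the tail fit.
#' @param min_tail_count smallest pool exceedance count at which the
#'   empirical survival is trusted over the fitted law.
#' @inheritParams apmi
#' @return an object of class `mi_null` with the intercept `a`, slope `b`
#'   (< 0) of the tail law, fit `r2`, the empirical survival table,
#'   `n_samples`, `n_perm` and `seed`.
#' @export
calibrate_null <- function(ranked, n_perm = 1e5, seed = 1, tail_frac = 0.05,
                           min_tail_count = 50,
                           chi2_crit = 7.815, min_points = 8) {
  stop_if_not_count(n_perm, "n_perm", min = 100)
  pool <- with_seed(seed,
    null_mi_pool_cpp(ranked, as.integer(n_perm), chi2_crit,
                     as.integer(min_points)))
  n <- length(pool)
  srt <- sort(pool, decreasing = TRUE)
  m <- max(ceiling(tail_frac * n), 25)
  x <- srt[seq_len(m)]
  surv <- seq_len(m) / n     # P(MI >= x_(i)) at the i-th largest value
  keep <- x > 0 & !duplicated(x, fromLast = TRUE)  # max rank per tie group
  x <- x[keep]; surv <- surv[keep]
  if (length(x) < 10)
    stop("null calibration degenerate: too few positive null MI values; ",
         "increase n_perm")
  fit <- lm(log10(surv) ~ x)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  if (!is.finite(b) || b >= 0)
    stop("null calibration failed (non-negative tail slope); ",
         "increase n_perm")
  r2 <- summary(fit)$r.squared
  # empirical survival on unique pooled values (ascending)
  ux <- sort(unique(pool))
  n_ge <- n - findInterval(ux, sort(pool), left.open = TRUE)
  structure(list(a = a, b = b, r2 = r2,
                 surv_x = ux, surv_p = n_ge / n,
                 emp_floor = min_tail_count / n,
                 n_samples = ncol(ranked),
                 n_perm = n_perm, seed = seed, tail_frac = tail_frac),
            class = "mi_null")
}

#' @export
print.mi_null <- function(x, ...) {
  cat(sprintf(
    "mi_null: log10 p = %.3f + (%.3f) * MI  (R2 = %.4f, %d permutations, N = %d)\n",
    x$a, x$b, x$r2, x$n_perm, x$n_samples))
  invisible(x)
}

#' P-value of an MI value under the calibrated null
#'
#' Uses the empirical permutation survival function where it can be
#' measured (at least `min_tail_count` pool values at or above `mi`, so
#' e.g. `p_of_mi(null, 0)` is exactly 1) and the fitted tail law
#' `10^(a + b*mi)` beyond the permutation floor. Values are clipped to
#' (0, 1].
#'
#' @param null an `mi_null`.
#' @param mi numeric vector of MI values (nats).
#' @return p-values in (0, 1].
#' @export
p_of_mi <- function(null, mi) {
  # S(mi) = P(null MI >= mi): step function over the unique pooled values
  j <- findInterval(mi, null$surv_x, left.open = TRUE) + 1
  s <- c(null$surv_p, 0)[pmin(j, length(null$surv_p) + 1)]
  p_line <- 10^(null$a + null$b * mi)
  p <- ifelse(s >= null$emp_floor, s, pmin(null$emp_floor, p_line))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' MI value at which the null reaches a given p-value
#' @param null an `mi_null`.
#' @param p target p-value.
#' @return MI in nats.
#' @export
mi_at_p <- function(null, p) {
  (log10(p) - null$a) / null$b
}

#' Infer the co-expression network by thresholding edge significance
#'
#' Computes MI for all protein pairs and keeps those whose p-value under
#' the calibrated null falls below `p_thresh` (default 1e-8, the edge
#' cutoff used throughout).
#'
#' @param m an [expression_matrix()] (complete; rank-transformed
#'   internally with the null model's seed) or a ranked matrix from
#'   [copula_rank_transform()].
#' @param null an `mi_null` calibrated on the same sample count.
#' @param p_thresh edge significance threshold.
#' @inheritParams apmi
#' @return a `pcn_network` whose nodes are all proteins of `m` and whose
#'   edges are the significant pairs (columns `a`, `b`, `mi`, `p`).
#' @export
infer_network <- function(m, null, p_thresh = 1e-8,
                          chi2_crit = 7.815, min_points = 8) {
  ranked <- if (inherits(m, "expr_matrix"))
    copula_rank_transform(m, seed = null$seed) else m
  if (ncol(ranked) != null$n_samples)
    warning("null model was calibrated for ", null$n_samples,
            " samples but matrix has ", ncol(ranked))
  pairs <- allpairs_mi(ranked, chi2_crit, min_points)
  pairs$p <- p_of_mi(null, pairs$mi)
  edges <- pairs[pairs$p < p_thresh, , drop = FALSE]
  new_network(rownames(ranked), edges,
              params = list(p_thresh = p_thresh, n_perm = null$n_perm,
                            seed = null$seed))
}

#' Prune indirect edges by the data-processing inequality
#'
#' For every triangle, the weakest edge is removed when its MI is strictly
#' below `(1 - tolerance)` times the minimum of the other two — the
#' classic heuristic for suppressing indirect dependencies. All triangles
#' are evaluated against the original MI values; marked edges are removed
#' afterwards, so the result does not depend on scan order.
#'
#' @param net a `pcn_network`.
#' @param tolerance in `[0, 1)`; 0 removes any strictly weakest edge.
#' @return a `pcn_network` with a subset of the input edges.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  if (tolerance < 0 || tolerance >= 1) stop("'tolerance' must be in [0, 1)")
  edges <- net$edges
  if (nrow(edges) < 3) return(net)
  g <- as_igraph(net)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  if (ncol(tri) == 0) return(net)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ids <- match(edges$a, net$nodes)
  jds <- match(edges$b, net$nodes)
  mi_of <- setNames(edges$mi, key(ids, jds))
  row_of <- setNames(seq_len(nrow(edges)), key(ids, jds))
  drop <- logical(nrow(edges))
  for (t in seq_len(ncol(tri))) {
    v <- tri[, t]
    k <- c(key(v[1], v[2]), key(v[1], v[3]), key(v[2], v[3]))
    w <- mi_of[k]
    weakest <- which.min(w)
    others <- min(w[-weakest])
    if (w[weakest] < others * (1 - tolerance))
      drop[row_of[k[weakest]]] <- TRUE
  }
  new_network(net$nodes, edges[!drop, , drop = FALSE],
              c(net$params, list(dpi_tolerance = tolerance)))
}

#' Keep the k highest-MI edges
#'
#' Edges are sorted by MI descending and the first `k` kept; any edge tied
#' with the k-th MI value is also kept (so the result can exceed `k`,
#' which is reported via a message).
#'
#' @param net a `pcn_network`.
#' @param k number of edges to keep (default 10000, the "top 0.1%"
#'   selection used for the large-scale network views).
#' @return a `pcn_network`; the node set is unchanged.
#' @export
top_k_edges <- function(net, k = 10000) {
  stop_if_not_count(k, "k")
  edges <- net$edges
  if (nrow(edges) <= k)
    return(new_network(net$nodes, edges[order(-edges$mi), , drop = FALSE],
                       c(net$params, list(top_k = k))))
  ord <- order(-edges$mi)
  cut <- edges$mi[ord[k]]
  keep <- ord[edges$mi[ord] >= cut]
  if (length(keep) > k)
    message(sprintf("top_k_edges: %d edges kept (ties at the k-th MI value)",
                    length(keep)))
  new_network(net$nodes, edges[keep, , drop = FALSE],
              c(net$params, list(top_k = k)))
}

#' Write and read edge lists
#'
#' TSV with columns `a`, `b`, `mi` and (if present) `p`; importable by
#' standard network tools.
#'
#' @param net a `pcn_network`.
#' @param path file path.
#' @return `path` / a `pcn_network`.
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  edges <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "mi") %in% colnames(edges)))
  new_network(unique(c(edges$a, edges$b)), edges)
}

#' Export a network in SIF format (`a mi b` per line)
#' @param net a `pcn_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  writeLines(paste(net$edges$a, "mi", net$edges$b), path)
  invisible(path)
}
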