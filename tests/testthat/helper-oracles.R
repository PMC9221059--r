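# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package's code paths.

# Plain-R adaptive-partitioning recursion over explicit point sets.
apmi_oracle <- function(x, y, chi2_crit = 7.815, min_points = 8) {
  N <- length(x)
  rec <- function(px, py, xlo, xhi, ylo, yhi, root) {
    n <- length(px)
    if (n == 0) return(0)
    xm <- (xlo + xhi) / 2
    ym <- (ylo + yhi) / 2
    q <- c(sum(px <= xm & py <= ym), sum(px > xm & py <= ym),
           sum(px <= xm & py > ym), sum(px > xm & py > ym))
    x2 <- sum((q - n / 4)^2 / (n / 4))
    if (n >= min_points && (x2 > chi2_crit || root)) {
      lo_x <- px <= xm; lo_y <- py <= ym
      return(rec(px[lo_x & lo_y], py[lo_x & lo_y], xlo, xm, ylo, ym, FALSE) +
             rec(px[!lo_x & lo_y], py[!lo_x & lo_y], xm, xhi, ylo, ym, FALSE) +
             rec(px[lo_x & !lo_y], py[lo_x & !lo_y], xlo, xm, ym, yhi, FALSE) +
             rec(px[!lo_x & !lo_y], py[!lo_x & !lo_y], xm, xhi, ym, yhi, FALSE))
    }
    p <- n / N
    p * log(p / ((xhi - xlo) * (yhi - ylo)))
  }
  max(0, rec(x, y, 0, 1, 0, 1, TRUE))
}

# Brute-force data-processing-inequality pruning by triple enumeration.
dpi_oracle <- function(edges, tolerance = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi_of <- setNames(edges$mi, key(edges$a, edges$b))
  nodes <- sort(unique(c(edges$a, edges$b)))
  drop <- setNames(rep(FALSE, nrow(edges)), key(edges$a, edges$b))
  if (length(nodes) >= 3) {
    for (tri in utils::combn(nodes, 3, simplify = FALSE)) {
      k <- c(key(tri[1], tri[2]), key(tri[1], tri[3]), key(tri[2], tri[3]))
      if (!all(k %in% names(mi_of))) next
      w <- mi_of[k]
      weakest <- which.min(w)
      if (w[weakest] < min(w[-weakest]) * (1 - tolerance))
        drop[k[weakest]] <- TRUE
    }
  }
  edges[!drop[key(edges$a, edges$b)], , drop = FALSE]
}

# Union-find connected-component sizes.
components_oracle <- function(edges, nodes) {
  parent <- setNames(nodes, nodes)
  find <- function(v) {
    while (parent[[v]] != v) v <- parent[[v]]
    v
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$a[i]); rb <- find(edges$b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# Trigamma inverse by bisection (monotone decreasing on (0, Inf)).
trigamma_inverse_bisect <- function(y, lo = 1e-6, hi = 1e8, tol = 1e-10) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < tol * mid) break
  }
  (lo + hi) / 2
}

# Exhaustive hypergeometric upper tail by direct summation of binomials.
ora_oracle <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Tiny undirected network builder for topology tests.
make_net <- function(edge_df, nodes = NULL, mi = NULL) {
  if (is.null(mi)) mi <- rep(1, nrow(edge_df))
  edges <- data.frame(a = pmin(edge_df[[1]], edge_df[[2]]),
                      b = pmax(edge_df[[1]], edge_df[[2]]),
                      mi = mi, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$a, edges$b))
  pcnet:::new_network(nodes, edges)
}

# k-clique edge list on the given node names.
clique_edges <- function(nodes) {
  cmb <- utils::combn(nodes, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

# Shared fixture: a small planted-module dataset with its inferred
# network, reused across community/statistics tests (built once per run).
planted_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synthetic_config(n_proteins = 120, n_tumor = 100, n_healthy = 3,
                            n_modules = 4, submodules_per_module = 1,
                            module_loading = 2, noise_sd = 1,
                            de_fraction = 0, missing_rate = 0, seed = 11)
    ds <- generate_dataset(cfg)
    tum <- ds$matrix$values[, samples_in_group(ds$matrix, "tumor")]
    rk <- copula_rank_transform(tum, seed = 12)
    nl <- calibrate_null(rk, n_perm = 5e4, seed = 13)
    net <- infer_network(rk, nl, p_thresh = 0.05 / choose(120, 2))
    cache <<- list(ds = ds, ranked = rk, null = nl, net = net)
    cache
  }
})
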