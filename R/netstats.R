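# Topology and annotation statistics of the co-expression network:
# degree distribution and its log-log power-law fit, per-subcommunity
# expression assortativity, cis/trans chromosomal edge classification and
# connected-component sizes.

#' Degree distribution of a network
#'
#' @param net a `pcn_network` with at least one node.
#' @return data.frame with columns `degree` and `count` (nodes with that
#'   degree); degrees with zero count are omitted and counts sum to the
#'   node count.
#' @export
degree_distribution <- function(net) {
  if (length(net$nodes) == 0) stop("empty network")
  deg <- setNames(rep(0L, length(net$nodes)), net$nodes)
  ends <- c(net$edges$a, net$edges$b)
  tb <- table(ends)
  deg[names(tb)] <- as.integer(tb)
  hist <- table(deg)
  data.frame(degree = as.integer(names(hist)), count = as.integer(hist))
}

#' Power-law fit of the degree distribution
#'
#' Ordinary least squares of `log10(count)` on `log10(degree)` over the
#' histogram points with degree >= 1 and count > 0, the conventional
#' log-log degree plot fit. Reports the slope (`alpha`), the Pearson
#' correlation of the fitted points (signed, and its absolute value as
#' usually quoted), and the points used. More rigorous tail-likelihood
#' approaches exist; this deliberately matches the plotted fit.
#'
#' @param hist data.frame from [degree_distribution()].
#' @return object of class `degree_fit` (list with `alpha`, `corr`,
#'   `corr_abs`, `n_points`, `points`), or `NULL` with a warning when
#'   fewer than 3 usable points exist.
#' @export
fit_power_law <- function(hist) {
  pts <- hist[hist$degree >= 1 & hist$count > 0, , drop = FALSE]
  if (nrow(pts) < 3) {
    warning("fewer than 3 histogram points; power-law fit skipped")
    return(NULL)
  }
  lx <- log10(pts$degree); ly <- log10(pts$count)
  fit <- lm(ly ~ lx)
  # Pearson r is undefined for an exactly flat (or single-degree) set
  r <- if (var(lx) == 0 || var(ly) == 0) NA_real_ else cor(lx, ly)
  structure(list(alpha = unname(coef(fit)[2]), corr = r, corr_abs = abs(r),
                 n_points = nrow(pts), points = pts),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("degree_fit: alpha = %.3f, |corr| = %.3f (%d points)\n",
              x$alpha, x$corr_abs, x$n_points))
  invisible(x)
}

#' Expression assortativity per subcommunity
#'
#' For each subcommunity, the fraction of its internal edges whose two
#' endpoints share the same differential-expression sign. Values near 1
#' mean the subcommunity is coherently over- or under-expressed; random
#' signs give values near 0.5. Only subcommunities with more than
#' `min_edges` internal edges are reported.
#'
#' @param net a `pcn_network`.
#' @param partition a `pcn_partition` with a `subcommunity` column.
#' @param signs named vector of +1/-1 per protein (e.g. the `sign` column
#'   of [de_analysis()] named by protein). Every network node must have
#'   one.
#' @param min_edges eligibility floor (strictly greater than; default 10).
#' @return data.frame: `subcommunity`, `n_edges`, `expass` in `[0, 1]`.
#' @export
expression_assortativity <- function(net, partition, signs, min_edges = 10) {
  miss <- setdiff(net$nodes, names(signs))
  if (length(miss))
    stop("nodes without an expression sign: ", paste(miss, collapse = ", "))
  if (!all(signs[net$nodes] %in% c(-1, 1)))
    stop("signs must be +1 or -1")
  sc_of <- setNames(partition$subcommunity, partition$protein)
  sa <- sc_of[net$edges$a]; sb <- sc_of[net$edges$b]
  within <- !is.na(sa) & !is.na(sb) & sa == sb
  agree <- signs[net$edges$a] == signs[net$edges$b]
  res <- lapply(sort(unique(sc_of)), function(sc) {
    idx <- within & sa == sc
    n <- sum(idx)
    if (n <= min_edges) return(NULL)
    data.frame(subcommunity = sc, n_edges = n,
               expass = sum(agree[idx]) / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(subcommunity = character(), n_edges = integer(),
                      expass = numeric())
  rownames(out) <- NULL
  out
}

#' Classify edges as cis (same chromosome) or trans
#'
#' @param net a `pcn_network`.
#' @param chrom_map named chromosome vector from [read_chromosome_map()].
#' @return list of class `cis_trans`: `n_cis`, `n_trans`, `n_unmapped`
#'   (edges with an endpoint absent from the map), `cis_fraction`
#'   (cis / mapped), and `per_chromosome` (data.frame of cis counts by
#'   chromosome).
#' @export
classify_cis_trans <- function(net, chrom_map) {
  ca <- chrom_map[toupper(net$edges$a)]
  cb <- chrom_map[toupper(net$edges$b)]
  unmapped <- is.na(ca) | is.na(cb)
  cis <- !unmapped & ca == cb
  trans <- !unmapped & ca != cb
  per <- if (any(cis)) {
    tb <- table(ca[cis])
    data.frame(chromosome = names(tb), n_cis = as.integer(tb))
  } else data.frame(chromosome = character(), n_cis = integer())
  structure(list(n_cis = sum(cis), n_trans = sum(trans),
                 n_unmapped = sum(unmapped),
                 cis_fraction = if (any(!unmapped))
                   sum(cis) / sum(!unmapped) else NA_real_,
                 per_chromosome = per),
            class = "cis_trans")
}

#' @export
print.cis_trans <- function(x, ...) {
  cat(sprintf("cis/trans: %d cis, %d trans, %d unmapped (cis fraction %.4f)\n",
              x$n_cis, x$n_trans, x$n_unmapped, x$cis_fraction))
  invisible(x)
}

#' Connected-component sizes
#'
#' @param net a `pcn_network`.
#' @return integer vector of component sizes, decreasing; sums to the
#'   node count (isolated nodes are size-1 components).
#' @export
component_sizes <- function(net) {
  if (length(net$nodes) == 0) return(integer(0))
  g <- as_igraph(net, weighted = FALSE)
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}
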