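# Hypergeometric over-representation analysis of subcommunities against
# gene-set collections (GO/KEGG-style GMT), with the conventional
# category-size window and Benjamini-Hochberg FDR control.

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realized overlap
#' between a query gene set and an annotated gene set, drawing without
#' replacement from the universe:
#' \eqn{p = \sum_{j \ge k} C(K,j) C(N-K, n-j) / C(N,n)}. Computed by the
#' exact hypergeometric tail (stable in log space).
#'
#' @param query character vector of query genes (e.g. one subcommunity).
#' @param geneset character vector of annotated genes.
#' @param universe character vector of all eligible genes; query/set
#'   members outside it are dropped with a warning.
#' @return one-row data.frame: `k` (overlap), `K` (set size in universe),
#'   `n` (query size in universe), `N` (universe size), `p`.
#' @export
ora <- function(query, geneset, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query); geneset <- unique(geneset)
  out_q <- setdiff(query, universe)
  out_s <- setdiff(geneset, universe)
  if (length(out_q) || length(out_s))
    warning(length(out_q) + length(out_s),
            " gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  geneset <- intersect(geneset, universe)
  k <- length(intersect(query, geneset))
  K <- length(geneset); n <- length(query); N <- length(universe)
  p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, K = K, n = n, N = N, p = p)
}

#' Enrich every subcommunity against gene-set collections
#'
#' Sets are first intersected with the universe; those with fewer than
#' `min_size` or more than `max_size` members are excluded before testing
#' (the standard 5-2000 category-size window). Within each subcommunity
#' the retained sets are tested by [ora()] and BH-adjusted; only
#' subcommunities with at least `min_mapped` genes in the universe are
#' tested. Records are sorted by `q` within subcommunity.
#'
#' @param partition a `pcn_partition` with a `subcommunity` column.
#' @param collections named list of gene sets (from [read_gmt()]), or a
#'   named list of such lists (multiple collections; names are prefixed).
#' @param universe background gene list; defaults to all proteins of the
#'   partition intersected with the collection's genes, which avoids
#'   composition bias from unmeasured genes. A genome-wide list can be
#'   passed instead.
#' @param min_size,max_size category-size window.
#' @param min_mapped minimum mapped query genes for a subcommunity test.
#' @param adjust `"subcommunity"` (BH within each subcommunity's tests,
#'   matching per-query web-tool behavior) or `"global"`.
#' @return data.frame: `subcommunity`, `set`, `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
enrich_partition <- function(partition, collections, universe = NULL,
                             min_size = 5, max_size = 2000, min_mapped = 3,
                             adjust = c("subcommunity", "global")) {
  adjust <- match.arg(adjust)
  if (!"subcommunity" %in% colnames(partition))
    stop("partition has no subcommunities; run subpartition() first")
  if (is.list(collections[[1]]))
    collections <- unlist(collections, recursive = FALSE)
  if (is.null(universe))
    universe <- intersect(toupper(partition$protein),
                          unique(toupper(unlist(collections))))
  universe <- unique(toupper(universe))
  sets <- lapply(collections, function(s) intersect(toupper(s), universe))
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  if (length(sets) == 0) {
    warning("no gene sets left inside the size window")
    return(data.frame(subcommunity = character(), set = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric()))
  }
  res <- list()
  for (sc in sort(unique(partition$subcommunity))) {
    query <- intersect(toupper(partition$protein[partition$subcommunity == sc]),
                       universe)
    if (length(query) < min_mapped) next
    rows <- do.call(rbind, lapply(names(sets), function(nm) {
      r <- ora(query, sets[[nm]], universe)
      cbind(data.frame(subcommunity = sc, set = nm,
                       stringsAsFactors = FALSE), r)
    }))
    if (adjust == "subcommunity") {
      rows$q <- bh_adjust(rows$p)
      rows <- rows[order(rows$q, rows$p), , drop = FALSE]
    }
    res[[sc]] <- rows
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(subcommunity = character(), set = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric()))
  if (adjust == "global") {
    out$q <- bh_adjust(out$p)
    out <- out[order(out$subcommunity, out$q, out$p), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Significance matrix for the enrichment heat map
#'
#' Rows are gene sets, columns subcommunities, cells `-log10(q)`;
#' cells with `q` above `q_cut` are blanked (`NA`), matching the
#' convention of whiting out non-significant cells.
#'
#' @param table output of [enrich_partition()].
#' @param q_cut significance cut (default 1e-5).
#' @return numeric matrix (possibly 0 x 0) of `-log10(q)`.
#' @export
enrichment_heatmap_table <- function(table, q_cut = 1e-5) {
  sig <- table[table$q <= q_cut, , drop = FALSE]
  if (nrow(sig) == 0)
    return(matrix(numeric(0), 0, 0))
  sets <- sort(unique(sig$set))
  scs <- sort(unique(sig$subcommunity))
  mat <- matrix(NA_real_, length(sets), length(scs),
                dimnames = list(sets, scs))
  mat[cbind(match(sig$set, sets), match(sig$subcommunity, scs))] <-
    -log10(sig$q)
  mat
}
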