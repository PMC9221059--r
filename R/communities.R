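# Two-level hierarchical community detection by greedy agglomerative
# modularity maximisation (communities are merged while modularity gains,
# then each community's induced subgraph is re-partitioned), producing
# mutually exclusive and exhaustive community / subcommunity labels.

#' Newman-Girvan modularity of a labeling
#'
#' \eqn{Q = \sum_i (e_{ii} - a_i^2)} over communities, where e_ii is the
#' fraction of edges inside community i and a_i the fraction of edge ends
#' attached to it (unweighted).
#'
#' @param net a `pcn_network` with at least one edge.
#' @param labels community labels, either named by node or in `net$nodes`
#'   order; must cover every node.
#' @return Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(net, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != length(net$nodes))
      stop("labels must cover all nodes")
    names(labels) <- net$nodes
  }
  miss <- setdiff(net$nodes, names(labels))
  if (length(miss)) stop("nodes without labels: ", paste(miss, collapse = ", "))
  m <- nrow(net$edges)
  if (m == 0) stop("network has no edges")
  la <- labels[net$edges$a]
  lb <- labels[net$edges$b]
  comms <- unique(labels[net$nodes])
  e_ii <- vapply(comms, function(cc) sum(la == cc & lb == cc) / m, numeric(1))
  ends <- c(la, lb)
  a_i <- vapply(comms, function(cc) sum(ends == cc) / (2 * m), numeric(1))
  sum(e_ii - a_i^2)
}

# number community labels 1, 2, ... by decreasing member count
relabel_by_size <- function(membership) {
  sizes <- sort(table(membership), decreasing = TRUE)
  new <- setNames(seq_along(sizes), names(sizes))
  unname(new[as.character(membership)])
}

fast_greedy_membership <- function(net) {
  g <- as_igraph(net, weighted = FALSE)
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
}

# Single-node reassignment sweeps: move each node (fixed lexicographic
# order) to the neighboring community with the largest positive
# modularity gain, until a full sweep makes no move. Incremental gain for
# moving v (degree k) from A to B: (l_vB - l_vA)/m - k(d_B - d_A + k)/(2m^2)
# with d_A taken including v.
local_moves <- function(net, memb) {
  m <- nrow(net$edges)
  if (m == 0) return(memb)
  nodes <- sort(names(memb))
  adj <- split(c(net$edges$b, net$edges$a), c(net$edges$a, net$edges$b))
  k_of <- lengths(adj)[nodes]
  k_of[is.na(k_of)] <- 0
  names(k_of) <- nodes
  d_c <- tapply(k_of, memb[nodes], sum)
  deg_sum <- setNames(as.numeric(d_c), names(d_c))
  for (sweep in 1:50) {
    moved <- FALSE
    for (v in nodes) {
      nb <- adj[[v]]
      if (is.null(nb)) next
      own <- memb[[v]]
      links <- table(memb[nb])
      l_own <- if (as.character(own) %in% names(links))
        links[[as.character(own)]] else 0
      best_gain <- 0; best_comm <- own
      for (cc in names(links)) {
        if (cc == as.character(own)) next
        gain <- (links[[cc]] - l_own) / m -
          k_of[[v]] * (deg_sum[[cc]] - deg_sum[[as.character(own)]] +
                         k_of[[v]]) / (2 * m^2)
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_comm <- as.integer(cc)
        }
      }
      if (best_comm != own) {
        memb[[v]] <- best_comm
        deg_sum[[as.character(own)]] <-
          deg_sum[[as.character(own)]] - k_of[[v]]
        deg_sum[[as.character(best_comm)]] <-
          deg_sum[[as.character(best_comm)]] + k_of[[v]]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

# Greedy modularity membership, refined and tie-broken:
# 1. agglomerative (fast-greedy) pass;
# 2. single-node reassignment sweeps (local_moves);
# 3. recursive-split refinement: re-run the greedy pass inside every
#    found community and accept the split whenever it raises global Q —
#    undoing the over-merges the agglomerative heuristic is prone to —
#    followed by further node sweeps, until Q stops improving;
# 4. ties toward coarseness: when the result does not beat the connected
#    components (e.g. a clique, where any split ties at Q = 0), the
#    coarser component partition is returned.
# Deterministic; communities numbered by decreasing size.
greedy_partition <- function(net) {
  memb <- local_moves(net, fast_greedy_membership(net))
  q_now <- modularity_q(net, memb)
  repeat {
    improved <- FALSE
    for (cc in sort(unique(memb))) {
      members <- names(memb)[memb == cc]
      if (length(members) < 4) next
      in_cc <- net$edges$a %in% members & net$edges$b %in% members
      if (!any(in_cc)) next
      subnet <- new_network(members, net$edges[in_cc, , drop = FALSE])
      split <- fast_greedy_membership(subnet)
      if (length(unique(split)) < 2) next
      cand <- memb
      cand[members] <- max(memb) + split[members]
      q_cand <- modularity_q(net, cand)
      if (q_cand > q_now + 1e-12) {
        memb <- cand
        q_now <- q_cand
        improved <- TRUE
      }
    }
    if (!improved) break
    memb <- local_moves(net, memb)
    q_now <- modularity_q(net, memb)
  }
  g <- as_igraph(net, weighted = FALSE)
  comp <- setNames(as.integer(igraph::components(g)$membership),
                   igraph::V(g)$name)
  if (q_now <= modularity_q(net, comp) &&
      length(unique(comp)) < length(unique(memb)))
    memb <- comp
  setNames(relabel_by_size(memb), names(memb))
}

#' Detect first-level communities by greedy modularity maximisation
#'
#' Fast-greedy agglomeration (starting from singletons, repeatedly merge
#' the pair of communities with the largest modularity gain) followed by
#' deterministic refinements on the same objective: single-node
#' reassignment sweeps and recursive splits accepted whenever they raise
#' global Q. Connected components are partitioned independently and
#' isolated nodes form singleton communities. Communities are numbered
#' by decreasing size.
#'
#' @param net a `pcn_network` with at least one edge.
#' @return object of class `pcn_partition`: data.frame with columns
#'   `protein` and `community`, modularity in attribute `q_level1`.
#' @export
detect_communities <- function(net) {
  if (nrow(net$edges) == 0) stop("cannot partition a network with no edges")
  memb <- greedy_partition(net)
  part <- data.frame(protein = net$nodes,
                     community = unname(memb[net$nodes]),
                     stringsAsFactors = FALSE)
  attr(part, "q_level1") <- modularity_q(net, setNames(part$community,
                                                       part$protein))
  class(part) <- c("pcn_partition", "data.frame")
  part
}

#' Split each community into subcommunities
#'
#' Reruns greedy modularity maximisation on every community's induced
#' subgraph. Communities that do not split (or have no internal edges)
#' yield a single subcommunity. Subcommunities are labeled
#' `"SC<community>_<k>"` with k numbered by decreasing size, are wholly
#' contained in their community, and jointly cover all nodes.
#'
#' @param net a `pcn_network`.
#' @param partition a level-1 `pcn_partition` from [detect_communities()].
#' @return the partition with an added `subcommunity` column; per-community
#'   modularities of the splits in attribute `q_level2`.
#' @export
subpartition <- function(net, partition) {
  if (!"community" %in% colnames(partition)) stop("level-1 partition required")
  sub <- character(nrow(partition))
  names(sub) <- partition$protein
  q2 <- list()
  for (cc in sort(unique(partition$community))) {
    members <- partition$protein[partition$community == cc]
    in_cc <- net$edges$a %in% members & net$edges$b %in% members
    sub_edges <- net$edges[in_cc, , drop = FALSE]
    if (nrow(sub_edges) == 0) {
      # no internal edges: every member is its own (or a single) subcommunity
      if (length(members) == 1) {
        sub[members] <- sprintf("SC%s_1", cc)
      } else {
        sub[members] <- sprintf("SC%s_%d", cc, seq_along(members))
      }
      next
    }
    subnet <- new_network(members, sub_edges)
    memb <- greedy_partition(subnet)
    sub[members] <- sprintf("SC%s_%d", cc, memb[members])
    q2[[as.character(cc)]] <- modularity_q(subnet, memb)
  }
  partition$subcommunity <- unname(sub[partition$protein])
  attr(partition, "q_level2") <- q2
  partition
}

#' Write a partition table to TSV
#' @param partition a `pcn_partition` (with or without subcommunities).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write.table(as.data.frame(partition), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
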