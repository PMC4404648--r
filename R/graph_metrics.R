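#' Reachability matrix of a directed network
#'
#' `reach[u, v]` is TRUE when v can be reached from u by a directed path of
#' length >= 1. The diagonal is TRUE only for nodes on a cycle (the empty
#' path does not count); self-loops are ignored throughout the asymmetry
#' metrics.
#'
#' @param net a `directed_network`.
#' @return a logical node-by-node matrix.
#' @export
reachability_matrix <- function(net) {
  stop_if_not_network(net)
  keep <- net$edges[, 1L] != net$edges[, 2L]
  g <- as_igraph(directed_network(
    if (any(keep)) net$edges[keep, , drop = FALSE] else NULL,
    nodes = net$nodes, quiet = TRUE))
  d <- igraph::distances(g, mode = "out")
  r <- is.finite(d) & d > 0
  # diagonal: a node reaches itself iff it lies on a directed cycle,
  # i.e. some out-neighbour reaches it
  adj <- d == 1
  diag(r) <- vapply(seq_len(nrow(r)), function(i) any(adj[i, ] & r[, i] | adj[i, i]),
                    logical(1))
  dimnames(r) <- list(net$nodes, net$nodes)
  r
}

pair_reach_counts <- function(net) {
  r <- reachability_matrix(net)
  n <- nrow(r)
  if (n < 2L)
    return(list(n_pairs = 0, connected = 0, both = 0, one = 0))
  up <- upper.tri(r)
  fwd <- r[up]                 # reach(i, j), i < j
  bwd <- t(r)[up]              # reach(j, i)
  list(n_pairs = sum(up),
       connected = sum(fwd | bwd),
       both = sum(fwd & bwd),
       one = sum(xor(fwd, bwd)))
}

#' Dyadic reciprocity
#'
#' The proportion of node pairs that are symmetric, i.e. reachable from
#' either direction. Following the connectedness-conditioned convention,
#' the denominator is the set of unordered pairs reachable in at least one
#' direction; the companion field `reciprocity_all_pairs` uses all n(n-1)/2
#' pairs instead. `one_minus_dr` (= 1 - reciprocity) is the asymmetry
#' measure commonly tabulated for directed networks.
#'
#' @param net a `directed_network` (self-loops ignored).
#' @return list with `reciprocity`, `one_minus_dr`, `reciprocity_all_pairs`,
#'   `n_connected_pairs`. When no pair is reachable in any direction the
#'   conditioned values are `NA` with a warning.
#' @export
dyadic_reciprocity <- function(net) {
  pc <- pair_reach_counts(net)
  if (pc$connected == 0) {
    warning("no reachable node pair: dyadic reciprocity undefined")
    rec <- NA_real_
  } else {
    rec <- pc$both / pc$connected
  }
  list(reciprocity = rec,
       one_minus_dr = 1 - rec,
       reciprocity_all_pairs = if (pc$n_pairs > 0) pc$both / pc$n_pairs else NA_real_,
       n_connected_pairs = pc$connected)
}

#' Krackhardt hierarchy score
#'
#' The fraction of node pairs reachable in exactly one direction — a
#' measure of the asymmetry of a directed network (1 on any DAG, 0 on a
#' fully mutual graph). Conditioned on pairs reachable in at least one
#' direction, with the unconditioned fraction exposed as `khs_all_pairs`.
#'
#' @param net a `directed_network` (self-loops ignored).
#' @return list with `khs`, `khs_all_pairs`, `n_connected_pairs`.
#' @export
krackhardt_hierarchy <- function(net) {
  pc <- pair_reach_counts(net)
  if (pc$connected == 0) {
    warning("no reachable node pair: Krackhardt hierarchy score undefined")
    khs <- NA_real_
  } else {
    khs <- pc$one / pc$connected
  }
  list(khs = khs,
       khs_all_pairs = if (pc$n_pairs > 0) pc$one / pc$n_pairs else NA_real_,
       n_connected_pairs = pc$connected)
}

#' Global reaching centrality
#'
#' The local reaching centrality C_R(i) of a node is the proportion of the
#' other N-1 nodes reachable from it; GRC is the average gap to the most
#' reaching node, sum_i (C_R^max - C_R(i)) / (N - 1). It is 1 for an
#' out-star (one node reaches everything, the rest reach nothing) and 0
#' when reaching is homogeneous.
#'
#' @param net a `directed_network` with at least 2 nodes.
#' @return list with `grc` and the per-node `local_reaching` vector.
#' @export
global_reaching_centrality <- function(net) {
  stop_if_not_network(net)
  n <- n_nodes(net)
  if (n < 2L)
    stop("global reaching centrality requires at least 2 nodes")
  r <- reachability_matrix(net)
  diag(r) <- FALSE
  cr <- rowSums(r) / (n - 1)
  list(grc = sum(max(cr) - cr) / (n - 1),
       local_reaching = cr)
}

#' All asymmetry metrics at once
#'
#' Convenience wrapper returning `one_minus_dr`, `khs` and `grc` in one
#' list, as typically tabulated side by side for network comparisons.
#'
#' @param net a `directed_network`.
#' @return list with fields `one_minus_dr`, `khs`, `grc`.
#' @export
asymmetry_metrics <- function(net) {
  list(one_minus_dr = dyadic_reciprocity(net)$one_minus_dr,
       khs = krackhardt_hierarchy(net)$khs,
       grc = global_reaching_centrality(net)$grc)
}
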