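#' Generate a perfect command hierarchy with planted levels
#'
#' Builds an L-level directed network in which every edge points strictly
#' downward under the planted assignment (so HS = +Inf and the network is
#' a DAG), in the style of a military command structure: a single
#' commander, widening levels below, orders flowing top to bottom only.
#'
#' In `tree` mode every node below the top receives exactly one parent from
#' the level immediately above; in `layered_random` mode extra downward
#' edges (between any higher/lower level pair) are added with probability
#' `extra_density` each. In both modes every non-bottom node is guaranteed
#' at least one subordinate in the level directly below and every non-top
#' node a superior directly above, so the planted assignment is the unique
#' all-downward levelling with L levels — the command chain through any
#' node spans the full depth.
#'
#' @param level_sizes node counts per level, given top level first
#'   (e.g. `c(1, 2, 4, 5, 7)` for a 19-node, 5-level pyramid).
#' @param branching `"tree"` or `"layered_random"`.
#' @param extra_density probability of each additional non-adjacent or
#'   duplicate-parent downward edge in `layered_random` mode.
#' @param seed integer RNG seed.
#' @return an object of class `planted_hierarchy`: list with `network`
#'   (a `directed_network`) and `truth` (the planted `level_assignment`,
#'   level 1 = bottom).
#' @examples
#' ph <- generate_perfect_hierarchy(c(1, 2, 4, 5, 7), seed = 1)
#' classify_edges(ph$network, ph$truth)  # all downward
#' @export
generate_perfect_hierarchy <- function(level_sizes,
                                       branching = c("tree", "layered_random"),
                                       extra_density = 0.15, seed = NULL) {
  branching <- match.arg(branching)
  level_sizes <- as.integer(level_sizes)
  L <- length(level_sizes)
  if (L < 2L) stop("need at least 2 levels")
  if (any(level_sizes < 1L)) stop("every level must contain at least one node")
  if (!is.null(seed)) set.seed(seed)

  # level index: 1 = bottom .. L = top; level_sizes arrives top-first
  sizes_bottom_first <- rev(level_sizes)
  nodes_by_level <- lapply(seq_len(L), function(lev)
    sprintf("L%d_%02d", lev, seq_len(sizes_bottom_first[lev])))
  nodes <- unlist(nodes_by_level)
  truth <- stats::setNames(rep(seq_len(L), sizes_bottom_first), nodes)

  edges <- list()
  for (lev in seq_len(L - 1L)) {          # children at lev, parents at lev+1
    children <- nodes_by_level[[lev]]
    parents <- nodes_by_level[[lev + 1L]]
    nc <- length(children); np <- length(parents)
    # every parent commands >= 1 child and every child obeys exactly one
    # parent (tree mode); guaranteed when nc >= np by seeding a matching
    pa <- character(nc)
    ord <- sample.int(nc)
    seedn <- min(nc, np)
    pa[ord[seq_len(seedn)]] <- sample(parents, seedn)
    if (nc > np)
      pa[ord[-seq_len(seedn)]] <- sample(parents, nc - np, replace = TRUE)
    edges[[lev]] <- cbind(pa, children)
    if (nc < np) {                        # narrower level below: childless
      spare <- setdiff(parents, pa)       # parents still need a subordinate
      if (length(spare))
        edges[[paste0("s", lev)]] <- cbind(spare,
                                           sample(children, length(spare),
                                                  replace = TRUE))
    }
  }
  em <- do.call(rbind, edges)

  if (branching == "layered_random" && extra_density > 0) {
    # candidate extra downward pairs: any strictly higher -> lower node
    cand <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    cand <- cand[truth[cand$from] > truth[cand$to], ]
    have <- paste(em[, 1L], em[, 2L])
    cand <- cand[!(paste(cand$from, cand$to) %in% have), ]
    take <- stats::runif(nrow(cand)) < extra_density
    if (any(take))
      em <- rbind(em, as.matrix(cand[take, ]))
  }

  structure(list(network = directed_network(em, nodes = nodes, quiet = TRUE),
                 truth = level_assignment(truth, L = L)),
            class = "planted_hierarchy")
}

#' @export
print.planted_hierarchy <- function(x, ...) {
  cat(sprintf("planted_hierarchy: %d levels, %d nodes, %d edges (all downward)\n",
              attr(x$truth, "L"), n_nodes(x$network), n_edges(x$network)))
  invisible(x)
}

#' Perturb a planted hierarchy with upward edges
#'
#' Randomly introduces `n_upward` new edges u -> v with
#' truth-level(u) < truth-level(v), sampled uniformly among the absent such
#' pairs; the original edges are untouched. In `"reverse"` mode existing
#' downward edges are flipped instead of new edges added.
#'
#' @param ph a `planted_hierarchy`.
#' @param n_upward number of upward perturbation edges (>= 0).
#' @param seed integer RNG seed.
#' @param mode `"add"` (default) or `"reverse"`.
#' @return a `directed_network`.
#' @export
perturb_with_upward_edges <- function(ph, n_upward, seed = NULL,
                                      mode = c("add", "reverse")) {
  mode <- match.arg(mode)
  if (!inherits(ph, "planted_hierarchy"))
    stop("expected a planted_hierarchy from generate_perfect_hierarchy()")
  n_upward <- as.integer(n_upward)
  if (n_upward < 0L) stop("n_upward must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  net <- ph$network
  if (n_upward == 0L) return(net)
  truth <- ph$truth

  if (mode == "reverse") {
    if (n_upward > n_edges(net))
      stop("cannot reverse ", n_upward, " of ", n_edges(net), " edges")
    idx <- sample.int(n_edges(net), n_upward)
    em <- net$edges
    em[idx, ] <- em[idx, c(2L, 1L)]
    return(directed_network(em, nodes = net$nodes, quiet = TRUE))
  }

  cand <- expand.grid(from = net$nodes, to = net$nodes,
                      stringsAsFactors = FALSE)
  cand <- cand[truth[cand$from] < truth[cand$to], ]
  cand <- cand[!(paste(cand$from, cand$to) %in%
                   paste(net$edges[, 1L], net$edges[, 2L])), ]
  if (nrow(cand) < n_upward)
    stop("only ", nrow(cand), " candidate upward pairs available, need ",
         n_upward)
  add <- cand[sample.int(nrow(cand), n_upward), ]
  directed_network(rbind(net$edges, as.matrix(add)), nodes = net$nodes,
                   quiet = TRUE)
}

#' Generate an Erdős–Rényi random digraph G(n, m)
#'
#' Samples exactly `n_edges` distinct ordered node pairs uniformly without
#' replacement — the null model used for hierarchy significance (same node
#' and edge counts as the network under test).
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of directed edges.
#' @param allow_self_loops include self-pairs among the candidates
#'   (default FALSE).
#' @param seed integer RNG seed.
#' @return a `directed_network` with nodes `"v1" ... "vn"`.
#' @export
generate_erdos_renyi <- function(n_nodes, n_edges, allow_self_loops = FALSE,
                                 seed = NULL) {
  n_nodes <- as.integer(n_nodes)
  n_edges <- as.integer(n_edges)
  if (n_nodes < 1L) stop("need at least one node")
  n_pairs <- if (allow_self_loops) n_nodes^2 else n_nodes * (n_nodes - 1L)
  if (n_edges > n_pairs)
    stop("cannot place ", n_edges, " edges over ", n_pairs, " ordered pairs")
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("v", seq_len(n_nodes))
  if (n_edges == 0L)
    return(directed_network(NULL, nodes = nodes))
  idx <- sample.int(n_pairs, n_edges) - 1L
  if (allow_self_loops) {
    from <- idx %/% n_nodes + 1L
    to <- idx %% n_nodes + 1L
  } else {
    # enumerate ordered pairs (i, j), i != j: row i owns n - 1 slots
    from <- idx %/% (n_nodes - 1L) + 1L
    off <- idx %% (n_nodes - 1L) + 1L
    to <- ifelse(off >= from, off + 1L, off)
  }
  directed_network(cbind(nodes[from], nodes[to]), nodes = nodes, quiet = TRUE)
}
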