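#' Annealing configuration for hierarchy score maximisation
#'
#' Bundles the simulated-annealing parameters. Sensible defaults are filled
#' per network at run time:
#' \itemize{
#'   \item `steps` (p): iterations per run, default `1200 * n_nodes * L`,
#'     chosen by the usual HS-versus-p saturation check: on the benchmark
#'     networks used here the best score stops improving well before this
#'     budget (re-examine the curve for much larger networks);
#'   \item `cooling` (alpha): geometric schedule `T_t = T0 * alpha^t`; the
#'     default alpha brings the temperature from `T0` down to `1e-3` over
#'     the `steps` iterations;
#'   \item `C`: the Boltzmann-like constant of the acceptance rule
#'     `P = exp(-dE / (C T))`.
#' }
#'
#' @param L number of hierarchical levels (>= 2).
#' @param runs number of independent annealing runs k aggregated into the
#'   probability matrix (default 1000).
#' @param steps iterations p per run, or NULL for the per-network default.
#' @param T0 initial temperature.
#' @param cooling geometric cooling rate alpha in (0, 1), or NULL for the
#'   default derived from `steps`.
#' @param C constant of the acceptance probability.
#' @param seed integer seed; run r uses `seed + r - 1`.
#' @param init optional named initial level assignment (e.g. from an
#'   external inference method) used as the starting point of every run
#'   instead of a uniformly random assignment.
#' @return an object of class `annealing_config`.
#' @export
annealing_config <- function(L, runs = 1000, steps = NULL, T0 = 1,
                             cooling = NULL, C = 1, seed = 1, init = NULL) {
  L <- as.integer(L)
  if (is.na(L) || L < 2L)
    stop("L must be an integer >= 2")
  if (runs < 1L) stop("runs (k) must be >= 1")
  if (!is.null(steps) && steps < 0) stop("steps (p) must be >= 0")
  if (!is.null(cooling) && (cooling <= 0 || cooling >= 1))
    stop("cooling rate alpha must lie in (0, 1)")
  if (T0 <= 0 || C <= 0) stop("T0 and C must be positive")
  structure(list(L = L, runs = as.integer(runs), steps = steps, T0 = T0,
                 cooling = cooling, C = C, seed = as.integer(seed),
                 init = init),
            class = "annealing_config")
}

resolve_config <- function(cfg, net) {
  n <- n_nodes(net)
  if (is.null(cfg$steps)) cfg$steps <- 1200L * n * cfg$L
  cfg$steps <- as.integer(cfg$steps)
  if (is.null(cfg$cooling))
    cfg$cooling <- if (cfg$steps > 0) (1e-3 / cfg$T0)^(1 / cfg$steps) else 0.5
  if (cfg$L > n)
    warning("L = ", cfg$L, " exceeds the number of nodes (", n,
            "); some levels will necessarily be empty")
  if (!is.null(cfg$init)) {
    iv <- as.integer(cfg$init)[match(net$nodes, names(cfg$init))]
    if (anyNA(iv) || any(iv < 1L) || any(iv > cfg$L))
      stop("'init' must assign every node a level in 1..L")
    cfg$init_vec <- iv
  } else {
    cfg$init_vec <- integer(0)
  }
  cfg
}

edge_indices <- function(net) {
  list(src = match(net$edges[, 1L], net$nodes) - 1L,
       dst = match(net$edges[, 2L], net$nodes) - 1L)
}

#' One simulated-annealing run
#'
#' Starts from a uniformly random level assignment (energy E0 = -HS0), then
#' repeatedly moves a random node to a random different level, accepting
#' score-improving moves outright and score-worsening moves with
#' probability `exp(-dE / (C T))` under geometric cooling. Returns the best
#' assignment visited and its hierarchy score. Score comparisons use exact
#' integer arithmetic, so a state with infinite HS (no upward, no
#' horizontal edge) is never exited.
#'
#' @param net a `directed_network` with at least one edge.
#' @param cfg an [annealing_config()].
#' @param run_seed RNG seed for this run (default `cfg$seed`).
#' @return list with `assignment` (a `level_assignment`) and `hs`
#'   (a `score_value`).
#' @export
anneal_once <- function(net, cfg, run_seed = cfg$seed) {
  stop_if_not_network(net)
  if (n_edges(net) == 0L)
    stop("cannot optimise the hierarchy of a network with no edges")
  cfg <- resolve_config(cfg, net)
  ei <- edge_indices(net)
  res <- anneal_runs_cpp(n_nodes(net), ei$src, ei$dst, cfg$L, cfg$steps, 1L,
                         cfg$T0, cfg$cooling, cfg$C, as.numeric(run_seed),
                         cfg$init_vec)
  asg <- level_assignment(stats::setNames(res$assignments[1L, ], net$nodes),
                          L = cfg$L)
  list(assignment = asg, hs = score_value(res$num[1L], res$den[1L]))
}

#' Infer the hierarchical structure of a directed network
#'
#' The full hierarchy-score-maximisation pipeline: `k` independent
#' simulated-annealing runs (seeds `seed, seed+1, ...`), aggregation of the
#' per-run optimal assignments into a node-by-level probability matrix
#' (entry = fraction of runs placing the node at the level), discretisation
#' by per-node argmax, and the three scores — HS of the best run, CHS of
#' the discretised assignment, and PHS computed from the probability
#' matrix.
#'
#' @param net a `directed_network` with at least one edge.
#' @param cfg an [annealing_config()]; alternatively pass `L` and friends
#'   via `...` and leave `cfg` NULL.
#' @param ... arguments forwarded to [annealing_config()] when `cfg` is NULL.
#' @return an object of class `hierarchy_result`: list with
#'   `best_assignment`, `probability_matrix`, `hs`, `chs`, `phs`,
#'   `per_run_scores` (list of `score_value`), `ties` (nodes whose argmax
#'   level was tied), `entropy` (per-node assignment entropy in nats, a
#'   degeneracy diagnostic) and `meta` (seed, p, k, schedule).
#' @examples
#' ph <- generate_perfect_hierarchy(c(1, 2, 4), seed = 1)
#' res <- run_hsm(ph$network, L = 3, runs = 25, seed = 1)
#' res$hs$value   # +Inf: every edge points downward
#' @export
run_hsm <- function(net, cfg = NULL, ...) {
  stop_if_not_network(net)
  if (is.null(cfg)) cfg <- annealing_config(...)
  if (!inherits(cfg, "annealing_config"))
    stop("cfg must come from annealing_config()")
  if (n_edges(net) == 0L)
    stop("cannot optimise the hierarchy of a network with no edges")
  cfg <- resolve_config(cfg, net)
  ei <- edge_indices(net)
  seeds <- cfg$seed + seq_len(cfg$runs) - 1
  res <- anneal_runs_cpp(n_nodes(net), ei$src, ei$dst, cfg$L, cfg$steps,
                         cfg$runs, cfg$T0, cfg$cooling, cfg$C,
                         as.numeric(seeds), cfg$init_vec)

  k <- cfg$runs
  n <- n_nodes(net)
  pm <- matrix(0, nrow = n, ncol = cfg$L,
               dimnames = list(net$nodes, paste0("level_", seq_len(cfg$L))))
  for (lev in seq_len(cfg$L))
    pm[, lev] <- colSums(res$assignments == lev) / k
  attr(pm, "L") <- cfg$L
  attr(pm, "k") <- k

  disc <- discretize(pm)
  per_run <- lapply(seq_len(k), function(r) score_value(res$num[r], res$den[r]))
  best <- per_run[[1L]]
  for (s in per_run) if (score_gt(s, best)) best <- s

  p_entropy <- apply(pm, 1L, function(p) {
    p <- p[p > 0]; -sum(p * log(p))
  })

  structure(list(
    best_assignment = disc$assignment,
    probability_matrix = pm,
    hs = best,
    chs = corrected_hierarchy_score(classify_edges(net, disc$assignment),
                                    level_sizes(disc$assignment)),
    phs = probabilistic_hierarchy_score(net, pm),
    per_run_scores = per_run,
    ties = disc$ties,
    entropy = p_entropy,
    significance = NULL,
    meta = list(seed = cfg$seed, p = cfg$steps, k = k, L = cfg$L,
                T0 = cfg$T0, cooling = cfg$cooling, C = cfg$C)
  ), class = "hierarchy_result")
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat(sprintf("hierarchy_result: %d nodes, L = %d, k = %d runs\n",
              nrow(x$probability_matrix), x$meta$L, x$meta$k))
  cat(sprintf("  HS  = %s\n  CHS = %s\n  PHS = %s\n",
              format(x$hs$value, digits = 6), format(x$chs$value, digits = 6),
              format(x$phs$value, digits = 6)))
  if (length(x$ties))
    cat("  tied argmax levels for:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

#' Discretise a probability matrix into a level assignment
#'
#' Each node goes to its maximum-probability level; ties are broken toward
#' the lower (more bottom) level index, deterministically, and the tied
#' nodes are reported.
#'
#' @param pm node-by-level probability matrix (rows sum to 1).
#' @return list with `assignment` (a `level_assignment`), `confidence`
#'   (per-node max probability) and `ties` (names of tied nodes).
#' @export
discretize <- function(pm) {
  pm <- as.matrix(pm)
  mx <- apply(pm, 1L, max)
  lev <- apply(pm, 1L, which.max)   # which.max takes the first (lowest) tie
  tied <- rownames(pm)[rowSums(pm == mx) > 1L]
  list(assignment = level_assignment(stats::setNames(as.integer(lev), rownames(pm)),
                                     L = ncol(pm)),
       confidence = stats::setNames(mx, rownames(pm)),
       ties = tied)
}

#' Choose the number of hierarchical levels
#'
#' Runs [run_hsm()] for each candidate L and picks the smallest L whose CHS
#' is within a relative tolerance of the maximum over the range (the
#' "saturating" L: increasing L further buys no real CHS improvement). HS
#' always grows with L and is not comparable across L, which is precisely
#' what CHS corrects. Candidate L values exceeding the network diameter
#' draw a warning (a hierarchy deeper than the longest shortest path is
#' hard to justify).
#'
#' @param net a `directed_network`.
#' @param L_range integer vector of candidate level counts (all >= 2).
#' @param cfg an [annealing_config()] whose `L` field is overridden per
#'   candidate; NULL for defaults.
#' @param tol relative CHS tolerance declaring saturation (default 0.02).
#' @param ... forwarded to [annealing_config()] when `cfg` is NULL
#'   (do not pass `L`).
#' @return list with `chosen_L`, `scores` (data frame of L, hs, chs, phs)
#'   and `results` (the per-L `hierarchy_result` objects).
#' @export
select_levels <- function(net, L_range = 2:8, cfg = NULL, tol = 0.02, ...) {
  stop_if_not_network(net)
  L_range <- sort(unique(as.integer(L_range)))
  if (length(L_range) == 0L) stop("empty L range")
  if (any(L_range < 2L)) stop("all candidate L must be >= 2")
  diam <- igraph::diameter(as_igraph(net), directed = TRUE)
  if (any(L_range > diam + 1))
    warning("candidate L beyond the network diameter (", diam,
            " edges): levels deeper than the longest geodesic")
  if (is.null(cfg)) cfg <- annealing_config(L = 2L, ...)

  results <- lapply(L_range, function(L) {
    cfg$L <- as.integer(L)
    run_hsm(net, cfg)
  })
  chs <- vapply(results, function(r) r$chs$value, numeric(1))
  best <- max(chs)
  saturated <- if (is.infinite(best)) is.infinite(chs) else chs >= (1 - tol) * best
  chosen <- L_range[which(saturated)[1L]]
  list(chosen_L = chosen,
       scores = data.frame(L = L_range,
                           hs = vapply(results, function(r) r$hs$value, numeric(1)),
                           chs = chs,
                           phs = vapply(results, function(r) r$phs$value, numeric(1))),
       results = results)
}
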