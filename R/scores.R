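#' Create a level assignment
#'
#' Maps every node to a hierarchical level in `1..L`, where level 1 is the
#' bottom and level `L` the top of the hierarchy (level i is higher than
#' level j when i > j). Empty levels are permitted.
#'
#' @param levels named integer vector, one entry per node.
#' @param L total number of levels; default `max(levels)`.
#' @return an integer vector of class `level_assignment` with attribute `L`.
#' @export
level_assignment <- function(levels, L = max(levels)) {
  if (is.null(names(levels)) || anyNA(names(levels)))
    stop("'levels' must be a named vector (names = node identifiers)")
  levels <- stats::setNames(as.integer(round(levels)), names(levels))
  if (anyNA(levels) || any(levels < 1L))
    stop("levels must be positive integers")
  L <- as.integer(L)
  if (L < max(levels))
    stop("L (", L, ") smaller than the largest assigned level (", max(levels), ")")
  structure(levels, L = L, class = "level_assignment")
}

#' @export
print.level_assignment <- function(x, ...) {
  cat(sprintf("level_assignment: %d nodes over L = %d levels (1 = bottom)\n",
              length(x), attr(x, "L")))
  print(table(factor(unclass(x), levels = seq_len(attr(x, "L")))))
  invisible(x)
}

#' Sizes of each level of an assignment
#' @param asg a `level_assignment`.
#' @return integer vector of length `L`: number of nodes per level, bottom first.
#' @export
level_sizes <- function(asg) {
  L <- attr(asg, "L")
  if (is.null(L)) L <- max(asg)
  tabulate(as.integer(asg), nbins = L)
}

#' Classify edges as downward, upward or horizontal
#'
#' Given a leveled digraph, an edge u -> v is *downward* when level(u) >
#' level(v), *upward* when level(u) < level(v) and *horizontal* when the two
#' levels coincide. Self-loops are horizontal by construction.
#'
#' @param net a `directed_network`.
#' @param asg a `level_assignment` (or named integer vector) covering every
#'   node of `net`.
#' @return an object of class `edge_class_counts`: list with integer fields
#'   `n_down`, `n_up`, `n_horizontal`.
#' @examples
#' net <- directed_network(rbind(c("T1", "B1"), c("T1", "B2")))
#' classify_edges(net, level_assignment(c(T1 = 2, B1 = 1, B2 = 1)))
#' @export
classify_edges <- function(net, asg) {
  stop_if_not_network(net)
  lv <- as.integer(asg)[match(net$nodes, names(asg))]
  if (anyNA(lv))
    stop("node(s) missing from the level assignment: ",
         paste(setdiff(net$nodes, names(asg)), collapse = ", "))
  names(lv) <- net$nodes
  a <- lv[net$edges[, 1L]]
  b <- lv[net$edges[, 2L]]
  structure(list(n_down = sum(a > b),
                 n_up = sum(a < b),
                 n_horizontal = sum(a == b)),
            class = "edge_class_counts")
}

#' @export
print.edge_class_counts <- function(x, ...) {
  cat(sprintf("edge classes: %d down, %d up, %d horizontal (total %d)\n",
              x$n_down, x$n_up, x$n_horizontal,
              x$n_down + x$n_up + x$n_horizontal))
  invisible(x)
}

#' Exact-ratio score values
#'
#' HS, CHS and PHS are ratios that legitimately reach +Inf (a perfectly
#' hierarchical network has no upward and no horizontal edges, so the HS
#' denominator vanishes). Scores therefore carry their exact numerator and
#' denominator alongside the floating value, and [score_gt()] compares two
#' scores by cross-multiplication so that infinite and near-equal values are
#' ordered without floating-point surprises.
#'
#' @param numerator,denominator the two non-negative components of the ratio.
#' @return an object of class `score_value` with fields `value`, `numerator`,
#'   `denominator`.
#' @export
score_value <- function(numerator, denominator) {
  if (numerator < 0 || denominator < 0)
    stop("score components must be non-negative")
  value <- if (denominator > 0) numerator / denominator
           else if (numerator > 0) Inf
           else NaN
  structure(list(value = value, numerator = numerator,
                 denominator = denominator), class = "score_value")
}

#' @export
print.score_value <- function(x, ...) {
  cat(sprintf("%s  (= %s / %s)\n", format(x$value, digits = 6),
              format(x$numerator), format(x$denominator)))
  invisible(x)
}

score_as_list <- function(s) {
  list(value = if (is.finite(s$value)) s$value else as.character(s$value),
       numerator = s$numerator, denominator = s$denominator)
}

#' @rdname score_value
#' @param a,b `score_value` objects (or plain numbers).
#' @export
score_gt <- function(a, b) {
  an <- if (inherits(a, "score_value")) a$numerator else a
  ad <- if (inherits(a, "score_value")) a$denominator else 1
  bn <- if (inherits(b, "score_value")) b$numerator else b
  bd <- if (inherits(b, "score_value")) b$denominator else 1
  an * bd > bn * ad
}

#' @rdname score_value
#' @export
score_eq <- function(a, b) {
  an <- if (inherits(a, "score_value")) a$numerator else a
  ad <- if (inherits(a, "score_value")) a$denominator else 1
  bn <- if (inherits(b, "score_value")) b$numerator else b
  bd <- if (inherits(b, "score_value")) b$denominator else 1
  an * bd == bn * ad
}

#' Hierarchy score
#'
#' HS = (Nd + Nh) / (Nu + Nh): the ratio of downward to upward edges,
#' balanced by the horizontal edges. It ranges from 0 to +Inf; when
#' Nu = Nh = 0 (every edge points down) the score is +Inf.
#'
#' @param counts an `edge_class_counts` from [classify_edges()], or a
#'   numeric vector `c(n_down, n_up, n_horizontal)`.
#' @return a `score_value`.
#' @export
hierarchy_score <- function(counts) {
  counts <- as_counts(counts)
  tot <- counts$n_down + counts$n_up + counts$n_horizontal
  if (tot == 0)
    stop("hierarchy score undefined for a network with no edges")
  score_value(counts$n_down + counts$n_horizontal,
              counts$n_up + counts$n_horizontal)
}

as_counts <- function(counts) {
  if (inherits(counts, "edge_class_counts")) return(counts)
  if (is.numeric(counts) && length(counts) == 3L)
    return(structure(list(n_down = counts[[1L]], n_up = counts[[2L]],
                          n_horizontal = counts[[3L]]),
                     class = "edge_class_counts"))
  stop("expected edge_class_counts or a numeric triple (down, up, horizontal)")
}

#' Expected edge-class counts under random edge placement
#'
#' For level sizes S_1..S_L (bottom to top) and edges placed uniformly over
#' ordered node pairs, the expected class totals are proportional to
#' E(Nd) = sum_{i>j} S_i S_j, E(Nu) = sum_{i<j} S_i S_j and
#' E(Nh) = sum_i S_i^2 (self-pairs included, which is where self-loops live).
#'
#' @param sizes non-negative integer vector of level sizes, bottom level first.
#' @return a list with fields `E_d`, `E_u`, `E_h`.
#' @examples
#' expected_edge_counts(c(2, 2))  # E_d = E_u = 4, E_h = 8
#' @export
expected_edge_counts <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (any(sizes < 0) || anyNA(sizes))
    stop("level sizes must be non-negative")
  tot <- sum(sizes)
  # sum_{i>j} S_i S_j = (tot^2 - sum S_i^2) / 2 by symmetry
  sq <- sum(sizes^2)
  off <- (tot^2 - sq) / 2
  list(E_d = off, E_u = off, E_h = sq)
}

#' Corrected hierarchy score
#'
#' CHS divides each observed edge-class count by its expectation given the
#' level sizes, making scores comparable across level counts L and across
#' networks:
#' CHS = (O(Nd)/E(Nd) + O(Nh)/E(Nh)) / (O(Nu)/E(Nu) + O(Nh)/E(Nh)).
#' It is about 1 for a random network and +Inf for a perfect hierarchy.
#' A ratio term with expectation 0 and observation 0 contributes 0 (such a
#' class is impossible under the assignment and indeed unobserved).
#'
#' @param counts an `edge_class_counts` (or numeric triple).
#' @param sizes level sizes of the assignment, bottom level first.
#' @return a `score_value`.
#' @export
corrected_hierarchy_score <- function(counts, sizes) {
  counts <- as_counts(counts)
  e <- expected_edge_counts(sizes)
  term <- function(obs, expct, what) {
    if (expct > 0) return(obs / expct)
    if (obs > 0)
      stop("observed ", what, " edges but their expected count is 0; ",
           "assignment and level sizes disagree")
    0
  }
  score_value(term(counts$n_down, e$E_d, "downward") +
                term(counts$n_horizontal, e$E_h, "horizontal"),
              term(counts$n_up, e$E_u, "upward") +
                term(counts$n_horizontal, e$E_h, "horizontal"))
}

#' Probabilistic hierarchy score
#'
#' When node levels are uncertain, each node carries a probability
#' distribution over the L levels (typically the run-frequency matrix from
#' [run_hsm()]). For an edge i -> j the probability of being downward is
#' sum over level pairs (a > b) of P(a, i) P(b, j), and analogously for
#' upward (a < b) and horizontal (a = b). PHS is then the HS ratio of the
#' summed per-edge probabilities. Self-loops are horizontal with
#' probability 1 (a node shares its own level whatever it is).
#'
#' @param net a `directed_network`.
#' @param pm numeric matrix of per-node level probabilities: rows named by
#'   node, one column per level (column 1 = bottom); each row must sum to 1.
#' @return a `score_value`.
#' @export
probabilistic_hierarchy_score <- function(net, pm) {
  stop_if_not_network(net)
  pm <- as.matrix(pm)
  if (n_edges(net) == 0L)
    stop("PHS undefined for a network with no edges")
  miss <- setdiff(net$nodes, rownames(pm))
  if (length(miss))
    stop("probability matrix missing node(s): ", paste(miss, collapse = ", "))
  rs <- rowSums(pm)
  if (any(abs(rs - 1) > 1e-9))
    stop("probability-matrix rows must sum to 1 (worst deviation ",
         format(max(abs(rs - 1))), ")")
  p_down <- p_up <- p_horiz <- 0
  for (k in seq_len(n_edges(net))) {
    i <- net$edges[k, 1L]; j <- net$edges[k, 2L]
    if (i == j) {               # self-loop: horizontal with certainty
      p_horiz <- p_horiz + 1
      next
    }
    pi <- pm[i, ]; pj <- pm[j, ]
    cum_j <- cumsum(pj)                      # P(level_j <= a)
    p_horiz <- p_horiz + sum(pi * pj)
    p_down <- p_down + sum(pi * (cum_j - pj))  # P(level_j < a) per a
    p_up <- p_up + sum(pi * (1 - cum_j))       # P(level_j > a)
  }
  score_value(p_down + p_horiz, p_up + p_horiz)
}
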