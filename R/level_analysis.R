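#' Band a level assignment into top / middle / bottom
#'
#' Downstream enrichment statistics work on three bands T, M, B. A 3-level
#' assignment maps directly (level 3 = T, 2 = M, 1 = B); deeper
#' hierarchies collapse by default to top level = T, bottom level = B and
#' everything between = M, or via a user-supplied level-to-band map.
#'
#' @param asg a `level_assignment`.
#' @param map optional character vector of length L giving the band
#'   (`"T"`, `"M"` or `"B"`) of each level, bottom level first.
#' @return named character vector node -> band.
#' @export
band_levels <- function(asg, map = NULL) {
  L <- attr(asg, "L")
  if (is.null(L)) L <- max(asg)
  if (is.null(map)) {
    if (L < 2L) stop("banding needs at least 2 levels")
    map <- c("B", rep("M", max(0L, L - 2L)), "T")
  }
  if (length(map) != L || !all(map %in% c("T", "M", "B")))
    stop("'map' must give T/M/B for each of the ", L, " levels")
  stats::setNames(map[as.integer(asg)], names(asg))
}

band_pair_sizes <- function(bands) {
  m <- c(T = sum(bands == "T"), M = sum(bands == "M"), B = sum(bands == "B"))
  pairs <- list(c("T", "T"), c("T", "M"), c("T", "B"),
                c("M", "M"), c("M", "B"), c("B", "B"))
  lab <- vapply(pairs, paste0, "", collapse = "")
  b <- vapply(pairs, function(p) {
    if (p[1L] == p[2L]) m[p[1L]] * (m[p[1L]] + 1) / 2 else m[p[1L]] * m[p[2L]]
  }, numeric(1))
  data.frame(label = lab, b = b, stringsAsFactors = FALSE)
}

normalize_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "character"
  pairs
}

#' Level-pair interaction enrichment
#'
#' Tests whether undirected interactions (physical, genetic, ...) among the
#' banded nodes are enriched or depleted within a band (TT, MM, BB) or
#' between bands (TM, TB, MB). Under the null, each of the `b` possible
#' pairs of a cell interacts independently with the background probability
#' p = e / (n (n - 1) / 2), where n is the universe size and e the total
#' interaction count. Intra-band cells count b = m (m + 1) / 2 possible
#' pairs (self-pairs included, the convention that accommodates
#' self-interactions); inter-band cells b = m1 m2. Enrichment P = P(X >= i)
#' and depletion P = P(X <= i) under Binomial(b, p).
#'
#' @param interactions two-column matrix/data frame of unordered node
#'   pairs; every endpoint must be banded.
#' @param bands named band vector from [band_levels()].
#' @param universe_n size n of the interaction universe (default: number of
#'   banded nodes).
#' @return data frame with one row per cell: `label`, `observed`,
#'   `possible_pairs`, `background_p`, `p_enrich`, `p_deplete`.
#' @export
level_pair_enrichment <- function(interactions, bands, universe_n = length(bands)) {
  interactions <- normalize_pairs(interactions)
  unbanded <- setdiff(as.vector(interactions), names(bands))
  if (length(unbanded))
    stop("interaction member(s) without a band: ",
         paste(unbanded, collapse = ", "))
  n <- universe_n
  e <- nrow(interactions)
  p <- e / (n * (n - 1) / 2)
  cells <- band_pair_sizes(bands)
  b1 <- bands[interactions[, 1L]]
  b2 <- bands[interactions[, 2L]]
  # canonical cell order is T < M < B, not alphabetical
  ord <- c(T = 1L, M = 2L, B = 3L)
  lab_obs <- ifelse(ord[b1] <= ord[b2], paste0(b1, b2), paste0(b2, b1))
  cells$observed <- vapply(cells$label, function(l) sum(lab_obs == l), numeric(1))
  cells$background_p <- p
  cells$p_enrich <- stats::pbinom(cells$observed - 1, cells$b, p,
                                  lower.tail = FALSE)
  cells$p_deplete <- stats::pbinom(cells$observed, cells$b, p)
  cells[, c("label", "observed", "b", "background_p", "p_enrich", "p_deplete")]
}

#' Cooperativity of nodes by shared interaction partners
#'
#' Two nodes are *cooperative* when they share significantly more partners
#' (physical, genetic or substrate) than expected: the overlap of their
#' partner sets is tested with the hypergeometric tail
#' P(overlap >= observed) given the two set sizes and the partner universe,
#' and called at `alpha`. Cooperative pairs are then tested for band-pair
#' enrichment with the binomial scheme of [level_pair_enrichment()], with
#' background probability = cooperative pairs / all tested pairs. Since a
#' node cannot cooperate with itself, intra-band cells here have
#' b = m (m - 1) / 2.
#'
#' @param partner_sets named list: node -> character vector of partners.
#' @param universe_n size of the partner universe.
#' @param bands named band vector covering `names(partner_sets)`.
#' @param alpha hypergeometric significance cut-off (default 0.05).
#' @return list with `pairs` (data frame of all tested pairs: node1, node2,
#'   overlap, p_overlap, cooperative) and `enrichment` (per-cell data frame
#'   as in [level_pair_enrichment()]).
#' @export
shared_partner_cooperativity <- function(partner_sets, universe_n, bands,
                                         alpha = 0.05) {
  nodes <- names(partner_sets)
  if (is.null(nodes)) stop("'partner_sets' must be a named list")
  sizes <- vapply(partner_sets, length, 1L)
  if (any(sizes > universe_n))
    stop("partner set larger than the universe")
  unbanded <- setdiff(nodes, names(bands))
  if (length(unbanded))
    stop("node(s) without a band: ", paste(unbanded, collapse = ", "))

  cmb <- utils::combn(nodes, 2L)
  ov <- integer(ncol(cmb)); pv <- numeric(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    a <- partner_sets[[cmb[1L, i]]]
    b <- partner_sets[[cmb[2L, i]]]
    ov[i] <- length(intersect(a, b))
    # P(overlap >= ov) drawing |b| partners from universe with |a| marked
    pv[i] <- stats::phyper(ov[i] - 1L, length(a), universe_n - length(a),
                           length(b), lower.tail = FALSE)
  }
  coop <- pv < alpha
  pairs <- data.frame(node1 = cmb[1L, ], node2 = cmb[2L, ], overlap = ov,
                      p_overlap = pv, cooperative = coop,
                      stringsAsFactors = FALSE)

  m <- c(T = sum(bands[nodes] == "T"), M = sum(bands[nodes] == "M"),
         B = sum(bands[nodes] == "B"))
  ord <- c(T = 1L, M = 2L, B = 3L)
  b1 <- bands[pairs$node1]; b2 <- bands[pairs$node2]
  lab <- ifelse(ord[b1] <= ord[b2], paste0(b1, b2), paste0(b2, b1))
  cell_lab <- c("TT", "TM", "TB", "MM", "MB", "BB")
  cell_b <- c(m["T"] * (m["T"] - 1) / 2, m["T"] * m["M"], m["T"] * m["B"],
              m["M"] * (m["M"] - 1) / 2, m["M"] * m["B"],
              m["B"] * (m["B"] - 1) / 2)
  p_bg <- sum(coop) / nrow(pairs)
  obs <- vapply(cell_lab, function(l) sum(lab == l & coop), numeric(1))
  enrichment <- data.frame(
    label = cell_lab, observed = obs, b = cell_b, background_p = p_bg,
    p_enrich = stats::pbinom(obs - 1, cell_b, p_bg, lower.tail = FALSE),
    p_deplete = stats::pbinom(obs, cell_b, p_bg),
    stringsAsFactors = FALSE)
  list(pairs = pairs, enrichment = enrichment)
}

#' Classify feed-forward loops by the hierarchy bands of their kinases
#'
#' A feed-forward loop is a triple (X, Y, Z): kinase X phosphorylates
#' kinase Y (edge X -> Y of the kinase network) and both phosphorylate a
#' common substrate Z (which may be any protein, Z distinct from X and Y).
#' Each motif is assigned to one of nine cells by the bands of X and Y
#' (TT, TM, TB, MT, MM, MB, BT, BM, BB); the X -> Y interaction is
#' downward in cells TM, TB, MB, upward in MT, BT, BM and horizontal in
#' TT, MM, BB. Every shared substrate counts as one motif.
#'
#' @param phospho_net a `directed_network` of kinase -> kinase edges
#'   (self-loops skipped: X and Y must differ).
#' @param substrate_map named list: kinase -> character vector of
#'   substrates.
#' @param bands named band vector covering the kinases.
#' @return list with `table` (3x3 matrix of counts, rows = band of X,
#'   cols = band of Y, in T, M, B order), `n_total`, and `direction_totals`
#'   (downward, upward, horizontal motif counts).
#' @export
classify_ffls <- function(phospho_net, substrate_map, bands) {
  stop_if_not_network(phospho_net)
  miss <- setdiff(phospho_net$nodes, names(substrate_map))
  if (length(miss))
    stop("kinase(s) without a substrate set: ", paste(miss, collapse = ", "))
  unbanded <- setdiff(phospho_net$nodes, names(bands))
  if (length(unbanded))
    stop("kinase(s) without a band: ", paste(unbanded, collapse = ", "))

  tab <- matrix(0L, 3L, 3L, dimnames = list(c("T", "M", "B"), c("T", "M", "B")))
  for (k in seq_len(n_edges(phospho_net))) {
    x <- phospho_net$edges[k, 1L]
    y <- phospho_net$edges[k, 2L]
    if (x == y) next
    z <- setdiff(intersect(substrate_map[[x]], substrate_map[[y]]), c(x, y))
    if (length(z))
      tab[bands[x], bands[y]] <- tab[bands[x], bands[y]] + length(z)
  }
  list(table = tab,
       n_total = sum(tab),
       direction_totals = c(
         downward = tab["T", "M"] + tab["T", "B"] + tab["M", "B"],
         upward = tab["M", "T"] + tab["B", "T"] + tab["B", "M"],
         horizontal = tab["T", "T"] + tab["M", "M"] + tab["B", "B"]))
}

#' Over-representation of self-loops
#'
#' Tests whether a network carries more self-loops (e.g. kinase
#' auto-phosphorylation) than expected if each of its e edges landed on a
#' uniformly random ordered node pair, self-pairs allowed, so that each
#' edge is a self-loop with probability 1/n. Upper-tail
#' Binomial(e, 1/n) P value.
#'
#' @param net a `directed_network`.
#' @return list with `observed`, `expected` (= e/n) and `p`.
#' @export
self_loop_overrepresentation <- function(net) {
  stop_if_not_network(net)
  n <- n_nodes(net)
  e <- n_edges(net)
  obs <- sum(net$edges[, 1L] == net$edges[, 2L])
  list(observed = obs,
       expected = e / n,
       p = stats::pbinom(obs - 1, e, 1 / n, lower.tail = FALSE))
}
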