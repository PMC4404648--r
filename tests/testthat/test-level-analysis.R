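band_fixture <- function(sizes = c(T = 2, M = 2, B = 2)) {
  nodes <- unlist(mapply(function(b, k) paste0(b, seq_len(k)), names(sizes),
                         sizes, SIMPLIFY = FALSE))
  stats::setNames(rep(names(sizes), sizes), nodes)
}

test_that("banding collapses deep hierarchies to T/M/B", {
  asg <- level_assignment(c(a = 5, b = 4, c = 3, d = 2, e = 1))
  expect_equal(unname(band_levels(asg)), c("T", "M", "M", "M", "B"))
  expect_equal(unname(band_levels(asg, map = c("B", "B", "M", "T", "T"))),
               c("T", "T", "M", "B", "B"))
  expect_error(band_levels(asg, map = c("B", "M", "T")), "each of the")
})

test_that("interaction enrichment reproduces the enumerated binomial tails", {
  # universe n = 4, e = 2 interactions, a band with m = 2 members holding
  # both: p = 1/3, b = 3, i = 2, so P(X >= 2) = 7/27 by direct enumeration
  bands <- c(A = "T", B = "T", C = "B", D = "B")
  inter <- rbind(c("A", "B"), c("A", "A"))
  cells <- level_pair_enrichment(inter, bands, universe_n = 4)
  tt <- cells[cells$label == "TT", ]
  expect_equal(tt$observed, 2)
  expect_equal(tt$b, 3)        # m (m + 1) / 2 with self-pairs
  expect_equal(tt$background_p, 1 / 3)
  expect_equal(tt$p_enrich, oracle_binom_upper(2, 3, 1 / 3))
  expect_equal(tt$p_enrich, 7 / 27)

  # an empty cell: depletion is the no-success mass, enrichment is certain
  bb <- cells[cells$label == "BB", ]
  expect_equal(bb$observed, 0)
  expect_equal(bb$p_deplete, (1 - 1 / 3)^3)
  expect_equal(bb$p_enrich, 1)

  expect_error(level_pair_enrichment(rbind(c("A", "Z")), bands, 4),
               "without a band")
})

test_that("binomial tails match exhaustive outcome enumeration up to b = 12", {
  set.seed(61)
  for (rep in 1:12) {
    b <- sample(1:12, 1)
    p <- runif(1, 0.05, 0.6)
    i <- sample(0:b, 1)
    expect_equal(stats::pbinom(i - 1, b, p, lower.tail = FALSE),
                 oracle_binom_upper(i, b, p), tolerance = 1e-12)
    expect_equal(stats::pbinom(i, b, p), oracle_binom_lower(i, b, p),
                 tolerance = 1e-12)
    # the two tails share the point mass at i
    expect_gte(stats::pbinom(i - 1, b, p, lower.tail = FALSE) +
                 stats::pbinom(i, b, p), 1)
  }
})

test_that("the fully concentrated cell is the most enriched", {
  bands <- band_fixture(c(T = 3, M = 3, B = 3))
  mm <- t(utils::combn(names(bands)[bands == "M"], 2))
  cells <- level_pair_enrichment(mm, bands, universe_n = 9)
  expect_equal(cells$p_enrich[cells$label == "MM"], min(cells$p_enrich))
})

test_that("cooperativity calls overlap significance correctly", {
  bands <- c(k1 = "T", k2 = "B", k3 = "B")
  universe <- paste0("s", 1:100)
  shared <- universe[1:5]
  out <- shared_partner_cooperativity(
    list(k1 = shared, k2 = shared, k3 = universe[10:12]),
    universe_n = 100, bands = bands)
  p12 <- out$pairs[out$pairs$node1 == "k1" & out$pairs$node2 == "k2", ]
  # identical 5-element sets: P = 1 / C(100, 5)
  expect_equal(p12$p_overlap, 1 / choose(100, 5))
  expect_true(p12$cooperative)
  p13 <- out$pairs[out$pairs$node1 == "k1" & out$pairs$node2 == "k3", ]
  expect_equal(p13$overlap, 0)
  expect_equal(p13$p_overlap, 1)
  expect_false(p13$cooperative)
})

test_that("hypergeometric overlap tails match subset enumeration", {
  # sets of sizes 3 and 4 in a universe of 20, overlap 2: enumerate every
  # placement of the second set against a fixed first set
  expect_equal(stats::phyper(2 - 1, 3, 17, 4, lower.tail = FALSE),
               oracle_hyper_upper(2, 3, 4, 20), tolerance = 1e-12)
  expect_equal(stats::phyper(0, 5, 15, 5, lower.tail = FALSE),
               oracle_hyper_upper(1, 5, 5, 20), tolerance = 1e-12)
})

test_that("feed-forward loops are counted per ordered band pair", {
  net <- directed_network(rbind(c("X", "Y")))
  bands <- c(X = "T", Y = "M")
  out <- classify_ffls(net, list(X = c("Z"), Y = c("Z")), bands)
  expect_equal(out$table["T", "M"], 1L)
  expect_equal(out$n_total, 1L)
  expect_equal(unname(out$direction_totals["downward"]), 1L)

  none <- classify_ffls(net, list(X = "Z1", Y = "Z2"), bands)
  expect_equal(none$n_total, 0L)

  # Z must be a third protein, and X -> X self-edges are no FFL
  self_sub <- classify_ffls(net, list(X = c("Y", "X"), Y = c("X", "Y")), bands)
  expect_equal(self_sub$n_total, 0L)
})

test_that("FFL counts equal a brute-force triple loop on a random fixture", {
  set.seed(62)
  kin <- paste0("K", 1:20)
  bands <- stats::setNames(sample(c("T", "M", "B"), 20, replace = TRUE), kin)
  net <- random_digraph(20, 45, seed = 63)
  names(bands) <- net$nodes
  subs <- lapply(stats::setNames(net$nodes, net$nodes), function(k)
    sample(c(net$nodes, paste0("sub", 1:30)), sample(3:10, 1)))
  out <- classify_ffls(net, subs, bands)

  brute <- 0L
  for (e in seq_len(n_edges(net))) {
    x <- net$edges[e, 1]; y <- net$edges[e, 2]
    if (x == y) next
    for (z in union(subs[[x]], subs[[y]]))
      if (z != x && z != y && z %in% subs[[x]] && z %in% subs[[y]])
        brute <- brute + 1L
  }
  expect_equal(out$n_total, brute)
  expect_equal(sum(out$table), brute)
  expect_equal(unname(sum(out$direction_totals)), brute)

  # permutation invariance of the totals under node relabeling
  perm <- stats::setNames(sample(net$nodes), net$nodes)
  net2 <- directed_network(cbind(perm[net$edges[, 1]], perm[net$edges[, 2]]),
                           nodes = unname(perm))
  subs2 <- lapply(subs, function(s) ifelse(s %in% names(perm), perm[s], s))
  names(subs2) <- perm[names(subs)]
  bands2 <- stats::setNames(bands, perm[names(bands)])
  out2 <- classify_ffls(net2, subs2, bands2)
  expect_equal(out2$n_total, out$n_total)
})

test_that("self-loop over-representation uses the uniform-pair binomial null", {
  # kinase-network scale: 94 nodes, 206 edges, 6 auto-interactions
  set.seed(64)
  nodes <- paste0("K", 1:94)
  em <- rbind(t(replicate(200, sample(nodes, 2))),
              cbind(nodes[1:6], nodes[1:6]))
  net <- directed_network(em, nodes = nodes, quiet = TRUE)
  out <- self_loop_overrepresentation(net)
  expect_equal(out$observed, 6L)
  expect_equal(out$expected, n_edges(net) / 94)
  # independent arithmetic for the upper tail of Binomial(e, 1/94)
  e <- n_edges(net)
  tail <- sum(choose(e, 6:e) * (1 / 94)^(6:e) * (93 / 94)^(e - 6:e))
  expect_equal(out$p, tail, tolerance = 1e-9)
  expect_lt(out$p, 0.05)  # clearly over-represented at this scale

  clean <- directed_network(rbind(c("a", "b"), c("b", "a")))
  expect_equal(self_loop_overrepresentation(clean)$p, 1)

  all_loops <- directed_network(rbind(c("a", "a"), c("b", "b")))
  expect_equal(self_loop_overrepresentation(all_loops)$p, (1 / 2)^2)
})
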