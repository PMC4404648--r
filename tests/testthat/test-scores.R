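test_that("edge classification follows the level order, self-loops horizontal", {
  net <- directed_network(rbind(c("T1", "B1"), c("T1", "B2")))
  down <- classify_edges(net, level_assignment(c(T1 = 2, B1 = 1, B2 = 1)))
  expect_equal(unclass(down)[c("n_down", "n_up", "n_horizontal")],
               list(n_down = 2L, n_up = 0L, n_horizontal = 0L))
  up <- classify_edges(net, level_assignment(c(T1 = 1, B1 = 2, B2 = 2)))
  expect_equal(up$n_up, 2L)
  expect_equal(up$n_down, 0L)

  loops <- directed_network(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
  flat <- classify_edges(loops, level_assignment(c(A = 1, B = 1), L = 2))
  expect_equal(flat$n_horizontal, 3L)

  expect_error(classify_edges(net, level_assignment(c(T1 = 2, B1 = 1))),
               "missing")
})

test_that("edge classes are conserved for arbitrary assignments", {
  for (seed in 1:25) {
    net <- random_digraph(sample(3:8, 1), sample(3:12, 1), seed = 200 + seed,
                          self_loops = TRUE)
    L <- sample(2:4, 1)
    cc <- classify_edges(net, random_assignment(net, L, seed = 300 + seed))
    expect_equal(cc$n_down + cc$n_up + cc$n_horizontal, n_edges(net))
  }
})

test_that("hierarchy score implements the balanced ratio with its +Inf limit", {
  expect_equal(hierarchy_score(c(4, 0, 0))$value, Inf)
  expect_equal(hierarchy_score(c(3, 1, 2))$value, 5 / 3)
  for (k in c(1, 4)) for (m in c(0, 3))
    expect_equal(hierarchy_score(c(k, k, m))$value, 1)
  expect_error(hierarchy_score(c(0, 0, 0)), "no edges")
})

test_that("HS is invariant to order-preserving relabels and inverts on reversal", {
  net <- random_digraph(6, 10, seed = 4)
  asg <- random_assignment(net, 3, seed = 5)
  hs <- hierarchy_score(classify_edges(net, asg))
  # squash levels 1,2,3 onto 1,3,7: order preserved, classes unchanged
  stretched <- level_assignment(stats::setNames(c(1L, 3L, 7L)[asg], names(asg)),
                                L = 7)
  expect_equal(hierarchy_score(classify_edges(net, stretched))$value, hs$value)
  # reversing the order swaps Nd and Nu; with Nh = 0 that maps HS to 1/HS
  cc <- classify_edges(net, asg)
  rev_hs <- hierarchy_score(c(cc$n_up, cc$n_down, 0))
  if (cc$n_horizontal == 0 && cc$n_up > 0)
    expect_equal(rev_hs$value, 1 / hs$value)
})

test_that("expected edge counts match the level-size sums", {
  expect_equal(expected_edge_counts(c(2, 2)), list(E_d = 4, E_u = 4, E_h = 8))
  expect_equal(expected_edge_counts(c(1, 1, 1)), list(E_d = 3, E_u = 3, E_h = 3))
  # independent double-loop arithmetic for the yeast-regulome-sized bands
  sizes <- c(62, 41, 42)
  ed <- 0; eh <- 0
  for (i in seq_along(sizes)) for (j in seq_along(sizes)) {
    if (i > j) ed <- ed + sizes[i] * sizes[j]
    if (i == j) eh <- eh + sizes[i] * sizes[j]
  }
  got <- expected_edge_counts(sizes)
  expect_equal(got$E_d, ed)
  expect_equal(got$E_u, ed)
  expect_equal(got$E_h, eh)
  expect_equal(c(ed, eh), c(6868, 7289))
  expect_error(expected_edge_counts(c(2, -1)), "non-negative")
})

test_that("corrected hierarchy score normalises by expectation", {
  expect_equal(corrected_hierarchy_score(c(3, 1, 2), c(2, 2))$value, 2)
  expect_equal(corrected_hierarchy_score(c(18, 0, 0), c(7, 5, 4, 2, 1))$value,
               Inf)
  # with equal level sizes at L = 2 the expectation terms cancel: CHS has
  # the same ordering content as HS (checked numerically on the ratio form)
  for (seed in 1:10) {
    nd <- sample(0:6, 1); nu <- sample(0:6, 1); nh <- sample(1:6, 1)
    chs <- corrected_hierarchy_score(c(nd, nu, nh), c(3, 3))
    e <- expected_edge_counts(c(3, 3))
    manual <- (nd / e$E_d + nh / e$E_h) / (nu / e$E_u + nh / e$E_h)
    expect_equal(chs$value, manual)
  }
})

test_that("CHS of a random assignment on a random digraph sits near 1", {
  set.seed(99)
  vals <- replicate(30, {
    net <- generate_erdos_renyi(60, 500, seed = sample.int(1e6, 1))
    asg <- random_assignment(net, 3, seed = sample.int(1e6, 1))
    corrected_hierarchy_score(classify_edges(net, asg),
                              level_sizes(asg))$value
  })
  expect_gt(mean(vals), 0.85)
  expect_lt(mean(vals), 1.15)
})

test_that("PHS reduces to HS for one-hot matrices and handles mixtures", {
  # single edge, split-level source: p_down = p_horiz = 0.5, PHS = 2
  net <- directed_network(rbind(c("i", "j")))
  pm <- rbind(i = c(0.5, 0.5), j = c(1, 0))
  expect_equal(probabilistic_hierarchy_score(net, pm)$value, 2)

  # uniform rows make down and up exchangeable: PHS = 1
  net2 <- random_digraph(6, 9, seed = 31)
  u <- matrix(1 / 3, nrow = 6, ncol = 3, dimnames = list(net2$nodes, NULL))
  expect_equal(probabilistic_hierarchy_score(net2, u)$value, 1)

  expect_error(probabilistic_hierarchy_score(net, rbind(i = c(0.6, 0.5),
                                                        j = c(1, 0))),
               "sum to 1")
})

test_that("PHS with a one-hot matrix equals HS on 100 random instances", {
  for (seed in 1:100) {
    net <- random_digraph(sample(3:7, 1), sample(3:10, 1), seed = 400 + seed,
                          self_loops = seed %% 5 == 0)
    L <- sample(2:4, 1)
    asg <- random_assignment(net, L, seed = 500 + seed)
    pm <- matrix(0, n_nodes(net), L, dimnames = list(net$nodes, NULL))
    pm[cbind(seq_len(n_nodes(net)), as.integer(asg))] <- 1
    phs <- probabilistic_hierarchy_score(net, pm)
    hs <- hierarchy_score(classify_edges(net, asg))
    expect_identical(phs$value, hs$value)
    expect_identical(phs$numerator, as.numeric(hs$numerator))
  }
})

test_that("adding an upward edge strictly decreases a finite HS", {
  for (seed in 1:15) {
    net <- random_digraph(6, 8, seed = 600 + seed)
    asg <- random_assignment(net, 3, seed = 700 + seed)
    cc <- classify_edges(net, asg)
    hs <- hierarchy_score(cc)
    if (!is.finite(hs$value)) next
    bumped <- hierarchy_score(c(cc$n_down, cc$n_up + 1, cc$n_horizontal))
    expect_true(score_gt(hs, bumped))
  }
})

test_that("exact score comparison orders infinite and near-equal ratios", {
  expect_true(score_gt(score_value(5, 0), score_value(100, 1)))
  expect_false(score_gt(score_value(5, 0), score_value(3, 0)))
  expect_true(score_eq(score_value(2, 6), score_value(1, 3)))
  expect_false(score_gt(score_value(1, 3), score_value(2, 6)))
})
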