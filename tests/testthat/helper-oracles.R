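# Independent brute-force oracles used to pin expected values.
# These deliberately avoid the package's own code paths: reachability by
# boolean matrix closure, score maxima by exhaustive enumeration of all
# L^n assignments, tail probabilities by explicit outcome enumeration.

oracle_reach <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    for (k in seq_len(nrow(net$edges))) {
      e <- net$edges[k, ]
      if (e[1] != e[2]) A[e[1], e[2]] <- TRUE
    }
  }
  R <- A
  for (i in seq_len(n)) R <- R | ((R %*% A) > 0)
  R
}

oracle_metrics <- function(net) {
  R <- oracle_reach(net)
  n <- nrow(R)
  both <- one <- conn <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    f <- R[i, j]; b <- R[j, i]
    if (f || b) {
      conn <- conn + 1L
      if (f && b) both <- both + 1L else one <- one + 1L
    }
  }
  cr <- (rowSums(R) - diag(R)) / (n - 1)
  list(reciprocity = if (conn) both / conn else NA_real_,
       khs = if (conn) one / conn else NA_real_,
       grc = sum(max(cr) - cr) / (n - 1))
}

# exhaustive maximum of HS = (Nd + Nh) / (Nu + Nh) over all L^n assignments
oracle_best_hs <- function(net, L) {
  n <- length(net$nodes)
  asg <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  src <- match(net$edges[, 1], net$nodes)
  dst <- match(net$edges[, 2], net$nodes)
  Nd <- Nu <- Nh <- numeric(nrow(asg))
  for (k in seq_along(src)) {
    a <- asg[, src[k]]; b <- asg[, dst[k]]
    Nd <- Nd + (a > b); Nu <- Nu + (a < b); Nh <- Nh + (a == b)
  }
  num <- Nd + Nh; den <- Nu + Nh
  val <- ifelse(den > 0, num / den, Inf)
  i <- which.max(val)
  list(num = num[i], den = den[i], value = val[i])
}

# exhaustive maximum of CHS over all L^n assignments (direct formula)
oracle_best_chs <- function(net, L) {
  n <- length(net$nodes)
  asg <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  src <- match(net$edges[, 1], net$nodes)
  dst <- match(net$edges[, 2], net$nodes)
  best <- -Inf
  for (r in seq_len(nrow(asg))) {
    lv <- asg[r, ]
    a <- lv[src]; b <- lv[dst]
    Nd <- sum(a > b); Nu <- sum(a < b); Nh <- sum(a == b)
    S <- tabulate(lv, nbins = L)
    Eh <- sum(S^2); Eoff <- (sum(S)^2 - Eh) / 2
    term <- function(o, e) if (e > 0) o / e else 0
    num <- term(Nd, Eoff) + term(Nh, Eh)
    den <- term(Nu, Eoff) + term(Nh, Eh)
    v <- if (den > 0) num / den else if (num > 0) Inf else NaN
    if (!is.nan(v) && v > best) best <- v
  }
  best
}

# upper-tail P(X >= i) of Binomial(b, p) by enumerating all 2^b outcomes
oracle_binom_upper <- function(i, b, p) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), b)))
  s <- rowSums(outcomes)
  pr <- p^s * (1 - p)^(b - s)
  sum(pr[s >= i])
}

oracle_binom_lower <- function(i, b, p) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), b)))
  s <- rowSums(outcomes)
  pr <- p^s * (1 - p)^(b - s)
  sum(pr[s <= i])
}

# P(|A intersect B| >= ov) for a fixed set A of size ka and B drawn
# uniformly among size-kb subsets of a universe of size N
oracle_hyper_upper <- function(ov, ka, kb, N) {
  sets <- utils::combn(N, kb)
  hits <- colSums(sets <= ka)   # A taken as {1..ka}
  mean(hits >= ov)
}

# uniformly random digraph fixture for oracle batteries
random_digraph <- function(n, m, seed, self_loops = FALSE) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  if (!self_loops) pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), min(m, nrow(pairs))), ]
  directed_network(as.matrix(pick), nodes = nodes, quiet = TRUE)
}

# a random level assignment over the nodes of a network
random_assignment <- function(net, L, seed) {
  set.seed(seed)
  level_assignment(stats::setNames(sample.int(L, n_nodes(net), replace = TRUE),
                                   net$nodes), L = L)
}
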