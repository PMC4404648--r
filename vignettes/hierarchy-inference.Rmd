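---
title: "Inferring hierarchy in directed networks with hsmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hierarchy in directed networks with hsmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Many directed biological networks — transcription-factor regulomes,
kinase–substrate phosphorylomes, food webs, neural wiring — are organised
as command structures: information or control flows predominantly from a
small set of master regulators at the top towards effectors at the bottom.
`hsmnet` infers that organisation directly from the wiring diagram, with
no annotation beyond the edge list, by arranging nodes into levels so that
a global *hierarchy score* is maximised.

## The model

Fix a number of levels $L$ and assign every node a level in $1..L$
(level 1 is the bottom; level $i$ is higher than level $j$ when $i > j$).
Each directed edge $u \to v$ is then

* **downward** if $\mathrm{level}(u) > \mathrm{level}(v)$,
* **upward** if $\mathrm{level}(u) < \mathrm{level}(v)$,
* **horizontal** if the levels coincide (self-loops are horizontal by
  construction).

Writing $N_d$, $N_u$, $N_h$ for the class counts, the hierarchy score is

$$HS = \frac{N_d + N_h}{N_u + N_h},$$

the ratio of downward to upward edges balanced by the horizontal ones. It
ranges from 0 to $+\infty$; a network admitting an assignment with
$N_u = N_h = 0$ (every edge points down) is perfectly hierarchical and
scores $+\infty$. The inferred hierarchy of a network is the assignment
maximising $HS$.

$HS$ grows mechanically with $L$ (more levels, more freedom), so scores at
different $L$ — or for different networks — are compared through the
*corrected hierarchy score*, which divides each observed class count by
its expectation if the same number of edges were thrown uniformly at
ordered node pairs given the level sizes $S_1..S_L$:

$$CHS = \frac{O(N_d)/E(N_d) + O(N_h)/E(N_h)}
             {O(N_u)/E(N_u) + O(N_h)/E(N_h)},
\qquad
E(N_d) = \sum_{i>j} S_i S_j,\;
E(N_u) = \sum_{i<j} S_i S_j,\;
E(N_h) = \sum_{i} S_i^2.$$

$E(N_h)$ counts self-pairs, which is where self-loops live. $CHS$ is
about 1 for a random arrangement and $+\infty$ for a perfect hierarchy.

Because loops can make the optimum non-unique, the final object is
probabilistic: $k$ independent optimisations are aggregated into a matrix
$P(\ell, i)$ = fraction of runs assigning node $i$ to level $\ell$. The
*probabilistic hierarchy score* applies the $HS$ ratio to the per-edge
probabilities of being downward / upward / horizontal implied by $P$, and
a discrete structure is recovered by per-node argmax.

## The optimiser

`run_hsm()` maximises $HS$ by simulated annealing: start from a uniformly
random assignment with energy $E = -HS$; repeatedly move a random node to
a random different level; accept improvements outright and deteriorations
with probability $P = \exp(-\Delta E / (C\,T))$ while the temperature
cools geometrically, $T_t = T_0\,\alpha^t$. The returned assignment is
the best ever visited, not the final state, which is robust to late
uphill acceptances.

Numerical choices that matter:

* **Exact score arithmetic.** Scores are kept as integer
  numerator/denominator pairs and compared by cross-multiplication, so
  $+\infty$ (denominator 0) needs no floating sentinel and a perfect
  state is never abandoned by the stochastic rule
  ($\Delta E = +\infty$). Equal scores accept the move (the landscape is
  explored across score-neutral plateaus).
* **Schedule defaults.** $T_0 = 1$, $C = 1$, and $\alpha$ chosen so the
  temperature ends at $10^{-3}$ after the $p$ steps of the run. All are
  configurable via `annealing_config()`.
* **Step budget.** The method's own calibration rule is to raise $p$
  until the achieved score saturates in $p$ and is stable across runs.
  On the 19-node five-level benchmark, $p = 200\,nL$ leaves roughly 10%
  of runs short of the known global optimum, $p = 600\,nL$ about 0.2%,
  and $p = 1200\,nL$ stalled zero times in 40,000 runs across ten planted
  topologies; the default is therefore $p = 1200\,nL$. For networks far
  larger than the thousand-node range examined here, re-examine the
  HS-versus-$p$ curve before trusting the default.
* **Reproducibility.** Run $r$ of $k$ uses seed `seed + r - 1` in a
  per-run RNG; identical configurations give bit-identical results.
* **Aggregation.** Probability rows are run fractions (multiples of
  $1/k$) over raw level indices, with no attempt to align permuted or
  shifted solutions between runs. When the optimum is degenerate (e.g. a
  structure that fits in fewer than $L$ levels can float), the mixing is
  visible in the per-node entropy diagnostic (`$entropy`) and in tied or
  flat probability rows; discretisation breaks ties toward the lower
  level, deterministically, and reports the tied nodes.
* **Empty levels** are legal: their $S_i = 0$ terms contribute nothing to
  the expectations, and a 0/0 class ratio contributes 0 to $CHS$.
* **Self-loops** are horizontal everywhere (they cannot be oriented by
  any assignment), and contribute horizontal probability 1 in $PHS$; the
  asymmetry metrics ignore them. We fix this convention rather than
  exposing a flag — no score comparison in the package mixes conventions.

## Choosing the number of levels

`select_levels()` scans a range (conventionally $L = 2..8$), runs the full
pipeline at each $L$, and picks the smallest $L$ whose $CHS$ is within a
relative tolerance (default 2%) of the range maximum — the "saturating"
$L$. On a perfect five-level pyramid the scan is unambiguous:

```{r levels, eval = FALSE}
library(hsmnet)
ph <- generate_perfect_hierarchy(c(1, 2, 4, 5, 7), seed = 1)
sel <- select_levels(ph$network, 2:8, runs = 100, seed = 42)
sel$scores
#>   L    hs      chs       phs
#> 1 2 1.875 2.301508  1.848999
#> 2 3 3.500 3.500000  2.702233
#> 3 4 9.000 7.562500  7.928118
#> 4 5   Inf      Inf       Inf
#> 5 6   Inf      Inf 13.441864
#> 6 7   Inf      Inf 10.490116
#> 7 8   Inf      Inf  7.517550
sel$chosen_L
#> [1] 5
```

At the true depth every run lands on the planted levels, the probability
matrix is one-hot and all three scores are infinite; deeper scans stay
infinite in $HS$/$CHS$ (an $L = 5$ solution embeds in $L = 6$) but $PHS$
drops because the embedding is degenerate across runs — a useful
fingerprint that 5 is the right depth. A warning is issued when
candidate $L$ exceed the network diameter.

## Significance

`assess_significance()` compares the optimised $HS$ with those of
Erdős–Rényi $G(n, m)$ digraphs with the same node and edge counts (edges
sampled uniformly without replacement; self-loop inclusion is a flag).
Per candidate $L$ it reports the empirical $P$ (fraction of null scores
$\ge$ observed), the Gaussian $Z = (HS - \mu)/\sigma$ with its
normal-tail $P$, the ratio $HS/\mu$ and a one-sample $t$ statistic; the
network-level $P$ is the minimum over $L$, Bonferroni-multiplied by the
number of $L$ tested. Both empirical and Gaussian scales are kept because
the null $HS$ distribution can be visibly non-normal for small sparse
networks.

Two calibration facts worth knowing:

* The optimised $CHS$ of a large sparse random digraph exceeds the
  theoretical random-assignment floor of 1 — maximisation capitalises on
  chance orientation. At $n = 1000$, $m = 2000$, $L = 3$ the optimised
  $CHS$ is near 2.7–2.9, still far below genuinely hierarchical
  networks; significance must therefore always come from the null
  comparison, never from the raw score.
* A *tree-sparse* perfect hierarchy ($m \approx n - 1$) is a weak test
  case: a random digraph that sparse is frequently acyclic and shallow
  enough to admit an all-downward levelling, i.e. the null itself reaches
  $HS = +\infty$. Denser hierarchies (the `layered_random` generator)
  do not have this problem — their nulls contain cycles almost surely.

## Downstream level statistics

With nodes banded into top/middle/bottom (`band_levels()`; deeper
hierarchies collapse middle levels by default, or supply a map):

* `level_pair_enrichment()` tests whether undirected interactions
  concentrate within or between bands under a
  $\mathrm{Binomial}(b, p)$ null with background
  $p = e / \binom{n}{2}$ and $b = m(m+1)/2$ possible intra-band pairs
  (self-pairs included, accommodating self-interactions) or $m_1 m_2$
  inter-band pairs; enrichment is $P(X \ge i)$, depletion $P(X \le i)$.
* `shared_partner_cooperativity()` calls two nodes cooperative when
  their partner sets overlap more than hypergeometrically expected
  ($P < 0.05$ by default), then applies the same binomial scheme to the
  cooperative pairs. Intra-band cells here use $m(m-1)/2$ — a node
  cannot cooperate with itself, so the self-pair slot of the interaction
  convention would be meaningless.
* `classify_ffls()` enumerates feed-forward loops — kinase $X$
  phosphorylates kinase $Y$, both phosphorylate a common substrate
  $Z \notin \{X, Y\}$ — and tallies them by the ordered band pair of
  $(X, Y)$ into the nine cells TT..BB; every shared substrate counts as
  one motif.
* `self_loop_overrepresentation()` tests auto-interaction counts against
  edges landing on uniform ordered pairs, i.e. an upper-tail
  $\mathrm{Binomial}(e, 1/n)$. The null is deliberately the simplest
  exchangeable one; it ignores degree heterogeneity, so treat small $P$
  values as descriptive when degrees are very skewed.

## What the generators emulate — and what they do not

`generate_perfect_hierarchy()` produces pyramidal command DAGs with a
planted truth: every node obeys exactly one superior in the level above
(tree mode, optionally densified with extra downward edges), and every
non-bottom node commands at least one subordinate in the level directly
below. That last guarantee makes the chain of command through every node
span the full depth, so the planted assignment is the *unique*
all-downward $L$-levelling — which is what lets recovery be tested
exactly. `perturb_with_upward_edges()` injects counter-hierarchical
edges against the planted truth; `generate_erdos_renyi()` is the null.

Real regulatory and phosphorylation networks differ from these fixtures
in ways the tests deliberately do not cover: heavy-tailed degrees,
autoregulatory loops, mutual (feedback) edges, incomplete and biased
interaction detection, and hierarchy depths that are not sharply defined.
Passing the recovery and calibration tests therefore shows the machinery
is correct, not that any particular biological network is hierarchical —
that question is exactly what the significance machinery is for.

## Problem sizes used in the shipped tests

The test-suite and benchmark computations are sized for a laptop-class
single core: recovery and level scans on the 19-node, 5-level pyramid
with $k = 100$ runs; exhaustive-oracle equivalence on digraphs of up to 8
nodes at $L = 3$ (at most $3^8$ assignments); perturbation decay with 20
replicates per perturbation count; null calibration with 200 nulls at
reduced per-null run counts; and one $n = 1000$, $m = 2000$ random
digraph at $k = 50$. These are study sizes, not limits; the annealing
core is compiled and handles thousand-node networks in seconds per run.

## Known limitations

* The annealing optimum carries no approximation guarantee; for networks
  much larger or denser than those studied here, verify saturation in
  $p$ and stability across $k$ before interpreting scores.
* Aggregation without run alignment means symmetric or under-constrained
  structures dilute the probability matrix (diagnosed, not corrected).
* The only null model shipped is $G(n, m)$; degree-preserving rewiring is
  a natural extension the interfaces leave room for.
* Published interaction datasets are not bundled; see the README for how
  to reproduce tabulated network comparisons from their sources.
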