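---
title: "Parsimony phylogenies from copy-number profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony phylogenies from copy-number profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnphylo)
```

## The event model

A tumor clone's chromosome is summarized by a *copy-number profile*
$\mathbf{y} = (y_1, \ldots, y_n)$: the non-negative number of copies of each
of $n$ ordered genomic positions. A healthy (diploid) chromosome is the
all-2's profile. Somatic evolution is modeled by *segmental events*
$(s, t, b)$: every position in the interval $[s, t]$ whose current value is
nonzero is changed by $b$, clamped below at zero; $b > 0$ is an
amplification, $b < 0$ a deletion, and the event costs $|b|$. Two
consequences shape everything downstream:

* **zero absorption** — once a position reaches copy number 0 it is frozen:
  it can be neither deleted further nor regained. The induced pairwise
  distance is therefore *asymmetric* (`cn_distance(c(2), c(0))` is 2, the
  reverse is infinite);
* **sortedness** — any event sequence can be replaced by one of no greater
  cost in which all deletions precede all amplifications. All solvers in the
  package work with sorted unit-event sequences, and decode per-position
  *coverage tracks* (deletion and amplification cost covering each
  position) into maximal-run unit events by skyline decomposition.

## Pairwise distance

`cn_distance(p, q)` is the minimum total cost of a sequence turning `p`
into `q`. It is computed by dynamic programming over states $(i, d, a)$
where $d$ and $a$ are the deletion and amplification cost covering position
$i$, both bounded by the largest input value $B$: feasibility at position
$i$ requires $d < p_i$ and $q_i = p_i - d + a$ when $q_i > 0$, and
$d \ge p_i$ when $q_i = 0$; moving from position $i-1$ to $i$ pays only for
*new* coverage, $\max(d - d', 0) + \max(a - a', 0)$. The distance is the
minimum over the final column.

The independent oracle `cn_distance_bfs()` runs breadth-first search over
the graph of all profiles with entries capped at $\max(p, q)$ whose arcs
are unit events. The test suite sweeps *all* profile pairs with $n \le 3$
and entries $\le 3$ and checks exact agreement; this also validates the
cap, which the recursion's budget range implies but which we verify rather
than assume.

## The triplet (median) problem

`cn_triplet(u, v)` finds a profile $\mathbf{m}$ and sorted event sequences
from $\mathbf{m}$ to $u$ and to $v$ of minimum total cost $\Delta(u, v)$.
Positions where both inputs are zero are removed first (the median is zero
there). The DP state extends the pairwise one to
$(i, m, d^u, a^u, d^v, a^v)$ — the median value and both budget pairs at
position $i$ — with all indices bounded by $B$; an optimal median never
needs entries above $B$, and an optional cap `e` tightens that bound to
$\min(B, e)$.

Two evaluation strategies are provided:

* `algorithm = "alg1"` keeps the complete table and supports traceback.
  The minimum over predecessor states of a sum of four
  $\max(x - x', 0)$ terms is evaluated exactly by a lower-envelope pass
  along each budget axis (a distance transform), which changes nothing
  about the recursion's values but removes a $B^5$ factor from each entry.
  Traceback re-derives an argmin chain by explicit enumeration, breaking
  ties toward the lexicographically smallest state so results are
  deterministic; the per-position budget tracks are then decoded into
  sorted unit events by skyline decomposition.
* `algorithm = "alg2"` computes the cost only, storing per level just the
  states consistent with the profile values (at a position with $u_i > 0$
  the amplification budget is determined, $a^u = u_i - m + d^u$) and
  enumerating restricted predecessors (when $u_{i-1} = 0$ one may fix
  $d^{u\prime} = \max(d^u, m')$ and $a^{u\prime} = a^u$; symmetrically for
  $v$). This is the fast path for long profiles.

Both are validated against `cn_triplet_brute()` — enumeration of every
candidate median scored by the BFS oracle — exhaustively at small scale,
and against each other on larger random instances.

## The tree problem

`cnt_solve()` addresses the general problem: given $k$ observed profiles
and a copy-number cap $e$, find a rooted full binary tree with the profiles
at its leaves, an all-2's root, every vertex entry at most $e$, and minimum
total event cost. The problem is NP-hard (see the hardness gadget below),
and is solved as an integer linear program over a supergraph on $2k - 1$
vertices that contains every full binary topology as a spanning tree:
binary arc variables select the topology (each non-root vertex one parent,
each internal vertex two children); integer variables $y_{i,s} \in
\{0..e\}$ label vertices, with indicators $\bar{y}_{i,s} = 1 \iff y_{i,s}
\neq 0$ enforced through a binary expansion; per-arc, per-position integer
tracks $a, d$ carry amplification and deletion coverage, constrained by a
four-way case analysis on $(\bar{y}_{i,s}, \bar{y}_{j,s})$ (balance
$y_{j,s} + d = y_{i,s} + a$ and $d < y_{i,s}$ when both endpoints are
nonzero; $d \ge y_{i,s}$ when the child is lost; losing-then-regaining
forbidden along selected arcs); and start-counting variables pay one unit
per new run, linearized with the arc indicator so only selected arcs
contribute to the objective. The case constraints are emitted for every
arc, selected or not — unselected arcs stay feasible through the big-M
terms and cost nothing — which follows the printed formulation rather than
gating constraints on arc selection.

Because a full binary root cannot have a single child, a second instance
augmented with an all-diploid profile is solved and the cheaper of the two
solutions returned (`augment = FALSE` disables this). The auxiliary leaf is
retained but flagged, and topology comparisons drop it. Note the augmented
optimum can never exceed the plain one — any plain tree extends by a
zero-cost diploid leaf at the root — so the plain solve contributes only
its (cheaper) tie-break preference and its lower bound.

Solutions are decoded into validated `cnt_tree` objects: selected arcs give
the topology, rounded $y$ values the profiles, and the $a, d$ tracks the
edge event sequences via skyline decomposition; `validate_tree()` then
mechanically re-checks every problem condition, so a solver or decoding
fault cannot silently produce an inconsistent tree. The exhaustive oracle
`cnt_brute()` (all topologies, all internal labelings, edges scored by
`cn_distance()`) confirms optimality on tiny instances.

### Solver backend

No mixed-integer solver is available in this R stack, so the model is
exported as JSON and solved by HiGHS through `scipy.optimize.milp` in a
`python` subprocess (`milp_python()` locates the interpreter;
`options(cnphylo.python = ...)` overrides). The solve is deterministic for
a fixed model, the default per-solve time limit is 600 s, and results
carry the solver status and dual bound so callers can distinguish proven
optima from time-limited incumbents.

## The hardness gadget

`mpp_to_cnt()` encodes maximum parsimony on binary vectors (Hamming
distance, all-zero root) as a copy-number tree instance with $e = 2$:
value 1 maps to copy number 1, value 0 to 2, and *walls* — alternating
$2, 1$ runs of length $nk$ — separate consecutive true positions so that,
at sufficient length, no affordable event spans two true positions. The
wall cells must be initialized once below the root, at fixed cost
$W = (n-1)nk/2$, and flips of true positions then correspond to unit
events, tying the two objectives together. The constructive direction —
tree cost at most parsimony cost plus $W$ — holds at every scale and is
asserted in the tests.

The exact *equality* of optima, however, is an asymptotic property: the
equivalence argument assumes $n \ge 4$, and at desk scale it genuinely
fails in two ways we verified by explicit certificates. Duplicate input
vectors let the tree place one shared internal vertex below the root and
serve both leaves (for $n = 1$, $b_1 = b_2 = (1)$: tree cost 1 versus
parsimony-plus-wall 2, because a 2-leaf parsimony tree has no internal
vertex to share), and a wall's trailing 1 is adjacent to the next true
position, so one deletion can initialize wall cells and flip a true
position together (for $b_1 = b_2 = (1,1)$: a validated tree of cost 3
versus 6). The acceptance test states the equality across all tiny
instances and is expected to fail there; the surrounding assertions pin
down what does hold.

## The simulator

`simulate_cnt(k, n, m, rho, seed)` reproduces the evaluation protocol:
a random full binary topology (grown by splitting a uniformly chosen leaf
until $k$ leaves exist, labels assigned by a uniform permutation); each
edge carries $d \sim \text{Uniform}\{1..m\}$ unit events with interval
drawn uniformly among the $n(n+1)/2$ pairs $s \le t$ and sign positive
with probability $\rho$; profiles propagate from the diploid root; and the
cap $e$ is the largest *leaf* entry, floored at 2. Three deliberate
consequences: events drawn over already-lost positions are no-ops yet
still count toward the simulated cost, so an inferred tree may cost less
than the simulation did; internal vertices may exceed the derived $e$, in
which case the truth tree itself may be infeasible for the solver while an
equally cheap or cheaper feasible tree still exists; and the generator
emulates clean integer profiles only — no measurement noise, fractional
copy numbers, clone mixtures, or multi-chromosome structure — so passing
tests speak to solver correctness, not to robustness on real tumor data.

## Topology evaluation

`normalized_rf()` compares leaf-labeled topologies by the symmetric
difference of clade sets over the total clade count, in $[0, 1]$. The
default compares *rooted* clades, the natural reading for trees rooted at
the diploid ancestor. The Robinson–Foulds metric as classically defined,
however, counts unrooted *splits*, and minimum-cost trees are not unique —
the root-edge placement among equal-cost trees is solver-arbitrary — so
the simulation-study summaries use `rooted = FALSE`, which scores
two trees identical exactly when their unrooted topologies agree. Both
conventions are exposed, and the unrooted path is cross-checked against
`phangorn::RF.dist` in the tests.

## Problem sizes used in the reproduction

`scripts/acceptance.R` regenerates the study at sizes chosen for a
single-CPU desk run. The topology-recovery batch uses $k = 4$ with the
full factorial $n \in \{20, 30, 40\} \times m \in \{1, 2, 3\} \times
\rho \in \{0.2, 0.4\}$ at one replicate per cell (18 instances), each
solved to proven optimality with both the plain and the augmented ILP; the
median split-based RF distance is reported. The cost-comparison batch uses
26 instances over $k \in \{4, 6\}$, $n \in \{10, 20\}$, solved to proven
optimality as the primary ILP (augmentation, which can only lower the
inferred cost, is omitted there, making the reported fraction of instances
with inferred cost at most simulated cost a conservative lower bound).
Larger grids — the full three-replicate protocol, or proven-optimal
augmented solves at $k = 6$ — multiply runtime several-fold without
changing what the statistics test.

## Numerical and degenerate-input choices

* Infinite distances use a sentinel larger than any feasible cost
  ($2nB$ bounds all finite values), so min-folds need no special cases.
* DP ties break toward lexicographically smallest states; solver ties are
  not controlled, and tests compare costs and validity, never one specific
  optimal tree.
* Profiles of length 1, all-zero pairs, and empty event sequences are all
  legal inputs; the triplet of two all-zero profiles has cost 0 and an
  all-zero median.
* MILP solutions are rounded to integers on decode and re-verified against
  the event semantics; a decoding inconsistency raises an error naming the
  arc and position rather than returning a silently wrong tree.

## Known limitations

Single chromosome only; integer copy numbers; no phasing; no clone-mixture
deconvolution. The ILP scales to roughly $k = 6$, $n = 40$ on one CPU with
the open-source backend; proving optimality for the augmented variant at
$k \ge 6$ can take much longer than finding the optimum. The triplet DP is
pseudo-polynomial: its table grows with $B^5$, so profiles with very large
copy numbers should go through the ILP-based tree solver instead.
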