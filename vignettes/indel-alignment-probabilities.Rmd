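---
title: "Ab initio alignment probabilities under a general indel model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ab initio alignment probabilities under a general indel model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelhist)
```

## The model

`indelhist` implements a continuous-time Markov model of sequence evolution
by insertions and deletions on *ancestry-indexed* sequence states.  Every
site carries an opaque token that it keeps for as long as it exists; newly
inserted sites draw fresh tokens.  Two sites in different sequences are
homologous exactly when they share a token, so the homology structure of an
alignment (its gap pattern and site correspondences — we never model
residues) is a deterministic function of the indel history, and conversely
every single-event transition between states is the action of a single
operator: an insertion `Ins(x, l)` of `l` sites after position `x`, or a
deletion `Del(xB, xE)` of positions `xB..xE`, clipped to the sequence when
it sticks out (the sequence is viewed as embedded in an effectively
infinite chromosome).

A *rate model* assigns instantaneous rates to all single-event channels
from a state; the total is the exit rate \(R_X^{ID}(s,t)\), whose time
integral gives the no-event retention probability.  The probability that a
fixed ordered history of \(N\) events occurred in a window \([t_I,t_F]\) is
a multiple-time integral over the ordered event timings: the product of the
per-step channel rates (each evaluated on the intermediate state the step
acts on) times a hypoexponential simplex integral of the inter-event exit
rates.  Summing over all histories consistent with an alignment — a
truncated perturbation expansion in the number of events — yields the
*ab initio* alignment probability, with no hidden-Markov or transducer
assumption anywhere.

## Equivalence classes and factorization

Sites present in both the ancestor and the descendant (preserved ancestral
sites, PASs) delimit regions that no event of a consistent history may
touch or cross.  Two temporally adjacent events in different regions can be
swapped after a coordinate shift — four binary relations cover the
insertion/deletion type combinations — and iterating the swaps sorts any
global history into its *local history set* (LHS): one local history per
region, with the within-region event order preserved.  An LHS class with
per-region event counts \(N_1,\dots,N_K\) contains
\(N!/\prod_k N_k!\) global histories (the order-preserving interleavings;
the package enumerates them by identity-tracked replay, resolving operator
coordinates from tokens rather than compounding shift arithmetic, and keeps
the symbolic swap chains as a test oracle).

The headline result the package operationalizes: the probability of an LHS
class factorizes into per-region multiplication factors — and hence the
whole alignment probability factorizes into an overall retention factor
times one factor per region, a generalized-HMM-like form — when

* **(i)** the rate of an event does not depend on the sequence content
  outside the event's region, and
* **(ii)** the exit-rate *increment* caused by an event does not depend on
  that outside content either.

Both conditions hold whenever the exit rate is affine in sequence length,
\(R = A\,L + B\), which is the case for all fully space-homogeneous
families.  For multiple alignments on a rooted tree a third condition is
needed: **(iii)** the root-state prior must be multiplicative across
regions relative to a reference root state; geometric and uniform length
priors satisfy it.  The package verifies all three conditions numerically
(`check_conditions()`, `check_root_prior_factorization()`): the conditions
quantify over an infinite state space, so the randomized probes are
falsification tests, not proofs — a "pass" means no witness was found at
tolerance `1e-9` over the sampled states.

## Built-in rate families and their parameters

* `homogeneous`: length-dependent rates `gI[l]`, `gD[l]` (events per site
  per unit time) with optional distinct end-insertion rates; cutoffs
  `L_I^CO = length(gI)`, `L_D^CO = length(gD)` truncate the length
  distributions.  Exit rate \(A L + B\) with
  \(A=\sum g_I+\sum g_D\),
  \(B=\sum(l-1)g_D-\sum g_I+\sum(g_{I;L}+g_{I;R})\).
* `dawg`: `gI = lambda_I * fI(l)`, `gD = lambda_D * fD(l)` with the end
  rates equal to the interior rate — the classic simulator
  parameterization.
* `long_indel`: the detailed-balance family; only `lambda1`, `mu1` and the
  deletion rates `mu[l]` are free, insertions follow
  \(\lambda_l=(\lambda_1/\mu_1)^l\mu_l\) with matching end and (at
  \(L=0\)) whole-sequence terms.  The whole-sequence insertion rate is
  implemented as \((\lambda_1/\mu_1)^l\sum_{l'\ge l} l'\mu_{l'}\) (the
  printed form of the weight, \(l'-1+1\), reduces to \(l'\)).
* `flanked`: space-homogeneous rates but deletions must fall entirely
  inside the sequence — biologically essential flanking regions forbid
  sticking out.  The exit rate is affine only for \(L \ge L_D^{CO}-1\);
  below that the model is the simplest example of condition (ii) failing
  while (i) holds, and the factorized and direct probabilities genuinely
  disagree (the package reports the gap rather than hiding it).
* `region_hetero`: a homogeneous baseline plus rate increments confined to
  tracked regions anchored as token sets on an initial state.  Events
  confined to distinct tracked regions or spacers still factorize; a PAS
  interior to a tracked region (or to a meta-region bridged by one
  deletion run) must not split a local history, which
  `decompose_regions()` honors through the model's merging hook.

Deletion rates are *defined* on raw windows (sticking-out included where
allowed); histories use effective clipped operators whose rate aggregates
all raw windows with the same action.  This is exact — identical-action
operators induce identical downstream evolution — and it keeps the affine
coefficients reproducible.  At \(L=0\) only insertion channels remain (the
whole-sequence term for `long_indel`, the left-end rate otherwise); the
affine form is asserted for \(L\ge 1\) because its channel counts
(\(L-1\) interior anchors, \(L+l-1\) deletion windows) presuppose a
nonempty sequence.

## Numerical choices

**Hypoexponential integrals.**  The timing integral of an \(N\)-event
history is \((-1)^N\) times the divided difference of \(e^{-RT}\) over the
\(N+1\) exit rates.  The textbook recursion cancels catastrophically when
rates nearly coincide; the package instead evaluates the divided difference
through its Opitz representation — the matrix exponential of a small upper
bidiagonal matrix holding the rates (`Matrix::expm`, scaling and squaring)
— which handles repeated and near-degenerate tuples without a branch
switch.  The recursive evaluator (with an explicit confluent branch
switching at relative spacing `1e-9`) is retained internally and in the
test suite as a cross-check, and nested adaptive quadrature
(`stats::integrate`, relative tolerance `1e-11`, \(N\le 4\)) and a
uniform-order-statistics Monte-Carlo route (with reported standard error)
serve as independent oracles.

**Time profiles.**  Constant rate profiles use the closed form throughout.
A piecewise-constant global rate multiplier is supported: retention
integrals are computed piecewise exactly, history probabilities route to
quadrature or Monte Carlo, and the simulator draws waiting times piece by
piece with memoryless carry-over.  General time dependence is out of
scope.

**Truncation.**  The expansion is truncated per region at the zone's
minimum event count (\(\lceil d/L_D^{CO}\rceil+\lceil i/L_I^{CO}\rceil\)
for \(d\) deleted and \(i\) inserted sites) plus a configurable slack
(default 1 extra event; "invisible" insert-then-delete round trips in
gapless zones enter once the slack is \(\ge 2\)).  The factorized and
direct routes are compared at *matched* truncation — identical per-zone
budgets — where the factorization identity is exact for condition-
satisfying models; this is how the package's tests distinguish a
truncation artifact from genuine non-factorability.  The reported residual
bound (a Poisson tail at the largest exit rate seen over the window) is a
heuristic indication, not a rigorous bound, since the state space is
unbounded.

**Degenerate inputs.**  Empty sequences, empty regions, zero rates,
zero-length branches and empty histories are all legal and covered by
tests; deletion operators with an empty clipped range are errors, as are
alignments whose shared tokens appear in different orders (rearrangements
are outside the model).

## The simulator and what the tests do (and do not) show

`gillespie_branch()` and `simulate_tree()` implement the exact stochastic
simulation algorithm of the same model: exponential waiting at the current
exit rate, channel choice proportional to aggregated effective rates,
per-branch substreams derived from `(seed, branch index)`.  Because
simulator and probability engine share one model definition but no code
path for the probability values themselves, agreement between simulated
homology frequencies and the truncated expansion (within Monte-Carlo
error) is a meaningful two-sided check; it is used for pairwise
probabilities at \(10^4\)–\(5\times10^4\) replicates and for a three-leaf
tree at \(2\times10^4\) replicates, with windows and rates chosen so the
truncated tail is far below the Monte-Carlo band.

The synthetic data are homology structures generated by the model itself:
they emulate the gap patterns, their spatial clustering, and the
phylogenetic correctness of real indel evolution, but not alignment error
(input alignments are assumed correct), rate heterogeneity beyond the
built-in families, substitutions, or rearrangements.  Passing tests
therefore validate the mathematics and the implementation, not the
adequacy of any particular rate family for a real dataset.

## Design decisions that were genuinely open

* **Canonical column order.**  Within a zone containing both deletions and
  insertions, deletion columns are emitted before insertion columns; for
  multiple alignments, columns that never co-occur in a row are ordered by
  a deterministic topological sort.  Any order consistent with every row is
  the same homology; fixing one makes equality testable.
* **Token allocation.**  Fresh tokens come from a global monotone integer
  counter.  Token values are arbitrary by construction, so all equality
  tests are relabel-invariant (`canonical_homology()`); the equivalence of
  interleaved histories is likewise asserted up to the labels of inserted
  sites.
* **Class counting.**  Order-preserving interleavings give the multinomial
  \(N!/\prod_k N_k!\); the package implements and enumerates exactly that
  (a denominator without factorials would disagree with the enumeration
  oracle for any \(N_k\ge 2\); see `?class_size`).
* **Region tracking for `region_hetero`.**  A tracked region's descendant
  interval is taken as the positional span of the surviving original
  tokens, a stateless rule computable from the model and the current state
  alone.  Sites inserted strictly inside the span are thereby inside the
  region; the rule differs from growing an explicit descendant-token set
  only after every original token on one flank has been deleted.
* **Reference root.**  The multiple-alignment factorization uses the Dollo
  parsimony root (a token is at the root iff its carriers span the root) —
  phylogenetically correct by construction and canonical.  Internal states
  introduce no tokens unobservable at every leaf by default
  (`limits = 0`); such states are higher order in the expansion, and the
  exact region-factor expression is validated against the direct
  ancestral-state sum, whose equality under conditions (i)–(iii) is the
  authoritative test.
* **Problem sizes.**  Worked examples use the 7-site ancestor; factorization
  identities are checked on that fixture and on 20 simulated alignments
  from 5–8-site ancestors; Monte-Carlo comparisons use the replicate counts
  quoted above.  These sizes keep every quantity exactly enumerable while
  exercising all code paths.

## Known limitations

Enumeration is exponential in the event budget and (for trees) in the
number of gapped columns, so the direct routes are desk-scale tools for
validation and small analyses, not genome-scale machinery.  The factorized
route is the scalable direction but still sums explicit local histories
per region.  Substitutions, residue emission, rearrangements, alignment
inference and rate-parameter estimation are out of scope.  Condition
checks are randomized falsification, not proof; and the truncation bound
is heuristic.
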