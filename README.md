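# indelhist

Ab initio alignment probabilities under a general continuous-time Markov
model of sequence evolution via insertions and deletions.

## What problem this solves, and for whom

Practically all probabilistic aligners and indel analyses assume up front
that an alignment's probability factorizes — into column-to-column HMM
transitions or transducer blocks.  A genuine evolutionary model makes no
such assumption: sequences evolve along a time axis under instantaneous
insertion/deletion rates, overlapping and compound events included, and the
probability of an alignment is the sum over *all* indel histories that
could have produced it.  `indelhist` is for method developers and
molecular-evolution researchers who want that first-principles quantity —
to compute it exactly at desk scale, to test when the familiar factorized
form is actually valid, and to measure how wrong it is when it is not.

The machinery rests on *ancestry indices*: each site carries an opaque
token for life, so a history is a well-defined series of operators
`Ins(x, l)` (insert `l` sites after position `x`) and `Del(xB, xE)`, and an
alignment is just the record of which tokens survived.  Events in different
inter-PAS regions (PAS = preserved ancestral site, present in ancestor and
descendant) commute up to a coordinate shift; sorting a history by region
yields its **local history set (LHS)**, and an LHS with per-region counts
\(N_1..N_K\) represents a class of \(N!/\prod_k N_k!\) equivalent global
histories.  A fixed history's probability is a hypoexponential simplex
integral of its exit rates; an alignment's probability is the truncated sum
over histories, organized as a direct sum over LHS classes:

    P[alignment] = sum over LHS classes of  P[class]
    P[class]     = P[no event] * prod over regions of mu_P[local history]
                   (the second line holds iff the model is "local":
                    condition (i)  — event rates ignore out-of-region context,
                    condition (ii) — exit-rate increments do too;
                    for trees, condition (iii) — the root prior is
                    multiplicative across regions)

Space-homogeneous families (including the Dawg simulator's model and the
long-indel detailed-balance model) satisfy (i)+(ii) because their exit rate
is affine in length, `R = A*L + B`.  A homogeneous model flanked by
essential regions violates (ii) below its deletion cutoff — the package
computes the resulting direct-vs-factorized gap instead of assuming it
away.  A Gillespie simulator of the same model provides true alignments
and an independent Monte-Carlo check of every probability.

## Worked example

The ancestor with ancestries `1..7` evolves into `1 5 6 8 9 10 7`
(sites 2–4 deleted, three sites inserted):

```r
library(indelhist)
ancestor   <- ancestry_seq(1:7)
descendant <- ancestry_seq(c(1, 5, 6, 8, 9, 10, 7))
pwa <- build_pwa(ancestor, descendant)
pwa
#> <pair_alignment 10 columns>
#>   anc : 1 2 3 4 5 6 - - - 7
#>   desc: 1 - - - 5 6 8 9 10 7
pas_set(pwa)
#> [1] 1 5 6 7
```

The PASs `1 5 6 7` delimit two non-empty regions: a three-site deletion
zone and a three-site insertion zone.  With length cutoffs of 3, two
events suffice, and exactly two operator sequences realize the alignment
parsimoniously:

```r
model <- make_builtin_model("dawg",
  list(lambda_I = 0.03, lambda_D = 0.04,
       fI = c(.6, .25, .15), fD = c(.5, .3, .2)))
min_events(pwa, model)
#> [1] 2
enumerate_global_histories(model, pwa, 2)
#> <history_enumeration 1 LHS classes, 2 histories, N_min=2, N_max=2>
```

— namely `Del(2,4) Ins(3,3)` and `Ins(6,3) Del(2,4)`, one LHS class.  A
four-event history sorts into its local history set and a class of
`4!/(2!2!) = 6` interleavings:

```r
lhs <- normalize_to_lhs(ancestor,
  list(op_del(3, 3), op_ins(5, 2), op_del(2, 3), op_ins(5, 1)))
lhs
#> <lhs K=2 N=4>
#>   k=1 (zone 1): Del(3,3), Del(2,3)
#>   k=2 (zone 3): Ins(6,2), Ins(8,1)
class_size(lhs)
#> [1] 6
```

The alignment probability over a unit time window, by the direct expansion
and by the factorized route at matched truncation:

```r
direct <- pwa_prob_direct(model, pwa, 0, 1, N_max = NULL,
                          n_max_per_region = c(1, 2, 1, 2, 1))
fact   <- pwa_prob_factorized(model, pwa, 0, 1,
                              n_max_per_region = c(1, 2, 1, 2, 1))
c(direct$value, fact$value)
#> [1] 2.412853e-05 2.412853e-05
```

The two agree to machine precision because this model passes the locality
probes:

```r
check_conditions(model, list(n = 200, seed = 1))
#> condition (i): pass  [tol 1e-09, 200 probes]
#> condition (ii): pass  [tol 1e-09, 200 probes]
```

Replacing the model with `make_builtin_model("flanked", ...)` on a short
sequence makes condition (ii) fail and the same two numbers separate — the
degree of non-factorability is quantified by `delta_delta_exit()`.

Tree-level analogues: `msa_prob_direct()` / `msa_prob_factorized()` with a
rooted `ape` tree, a root prior (`root_prior("geometric", q = ...)`), the
Dollo reference root (`dollo_root_state()`) and the condition-(iii) probe
(`check_root_prior_factorization()`).  `simulate_tree()` generates true
alignments under the same model.  A command-line wrapper `exec/indelhist`
exposes `simulate`, `pwa-prob`, `msa-prob`, `lhs-decompose` and
`check-conditions` over JSON configs and reports.

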