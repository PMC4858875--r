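---
title: "Self-learning 1H chemical shift prediction and assignment"
author: "hoseNMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-learning 1H chemical shift prediction and assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoseNMR)
```

## The problem

Semi-empirical 1H chemical shift prediction needs a database of assigned
protons; assigning a spectrum, in turn, is far easier when predicted
shifts are available. hoseNMR closes this circle without any
human-assigned training data: a combinatorial assigner that works from
peak integrals alone produces *consensus* assignments — nucleus–shift
pairs common to every feasible solution of a molecule, hence safe to
treat as correct — and those seed a fragment–shift database. In later
passes the database supplies shift windows that prune the assignment
search, which yields more consensus pairs, which grow the database. The
two halves bootstrap each other.

## The predictor

Each database entry couples a molecular fragment with an observed shift.
The fragment is the *n-sphere* of a proton — the substructure spanned by
all atoms up to `n` bonds from it — serialised as a canonical HOSE-style
string (Hierarchically Ordered Spherical description of Environment).
Radii are counted from the proton itself, so radius 1 is the attached
heavy atom; the alternative convention (counting from the attached
carbon) would shift every radius by one, and the choice is fixed here
once and used consistently on both the write and the read side of the
database.

A query spans the sphere of radius $n_\max$ (default 4) around the
proton and looks for exact code matches. On a miss the radius is reduced
one step at a time; below $n_\min$ (default 2) the prediction fails.
On a hit with $m$ matching entries carrying shifts
$\delta_1,\dots,\delta_m$ the predictor returns the median
$\bar\delta$ as the predicted shift and their sample standard deviation
$\varepsilon$ as its uncertainty ($\varepsilon$ is undefined for
$m = 1$). The sample ($m-1$ denominator) convention is deliberate: it is
the more conservative estimator at small $m$, and small $m$ dominates
early training. Radius-2 spheres are kept as the lower bound because
1-spheres collapse almost all protons onto a handful of codes and carry
no usable information.

### The HOSE dialect

No byte-level grammar is standardised across implementations, and the
learning loop only ever compares codes produced by its own encoder, so
internal consistency is what matters. The dialect here writes an atom as
`symbol[Hk][±q]` (attached-hydrogen count, formal charge), followed by a
parenthesised, comma-separated, lexicographically sorted list of
branches; a branch is a bond symbol (`-`, `=`, `#`, `:` aromatic)
followed by the next-shell atom's code, or `&` for a ring-closure bond
inside a shell. Atoms reachable along several shortest paths are
expanded under each predecessor. Sorting every branch list makes the
code independent of atom input order; the suite checks this by
re-encoding randomly relabelled molecules, and checks that code equality
at saturating radius coincides with the automorphism-orbit partition of
the protons.

Proton equivalence itself is computed by Morgan-style iterative
neighbourhood-label refinement. Refinement can in principle over-merge
on pathological regular graphs; a brute-force automorphism enumeration
serves as the test oracle on all fixture molecules to bound that risk.
Stereochemistry is ignored throughout — codes are constitution-only, so
diastereotopic protons fall in one class.

## The assigner

Assignment maps proton *equivalence classes* (never individual protons)
to peaks. Raw integrals are arbitrary-unit, so they are first rescaled
to sum to the molecule's proton count and rounded half-away-from-zero;
a molecule whose rounded integrals cannot balance is skipped. A
solution must balance exactly: the class sizes mapped to each peak sum
to its integer integral, which permits several classes on one peak
(overlapping signals). When the database supplies a prediction for a
class, the class may only sit on peaks within

$$ 3\,\varepsilon\,\bigl(1 + m^{-I/2}\bigr) $$

ppm of the predicted shift, where $I$ is the current iteration. The
factor $1 + m^{-I/2}$ inflates the raw uncertainty while the database
is young — it starts at 2 and decays towards 1, faster for larger
samples — because a standard deviation over two or three observations
is a poor uncertainty estimate and an over-tight window would propagate
early mistakes. Predictions based on fewer than two matches get a flat
20 ppm window (effectively unconstrained): no usable uncertainty exists
there. The threshold is configurable to "fewer than three" for a
stricter variant (`lowMatchThreshold = 3`).

The search is a branch-and-bound over classes, most-constrained class
first; the heuristic affects speed only, and an exhaustive-enumeration
oracle asserts set-equality of solutions on hundreds of random
problems. Enumeration is complete — the consensus step needs the whole
solution space — so a cap (default 10 000 solutions) guards against
factorial blow-ups; an overflowed molecule contributes nothing in that
iteration rather than contributing unreliable consensus pairs.

### Consensus and learning

From the full solution set, the class→peak pairs present in *every*
solution are extracted as consensus dyads and committed to the database
at radii $n_\min..n_\max$. Updates are batch-wise: all molecules of an
iteration are assigned against the database frozen at the start of the
iteration, and the harvest is committed at the end, so nothing learnt
in a pass is visible within it. Batch semantics make the end-of-
iteration database independent of the training-set order (asserted as a
set-equality property test). Iteration 0 runs with integral constraints
only. Entries deduplicate on (code, radius, shift, molecule), so
re-deriving a known dyad is a no-op; "two consecutive iterations add no
new entries" is therefore a monotone stopping signal, used together
with an iteration cap of 10.

The `excludeLabile` switch (default off) suppresses learning from
protons bonded to O, N or S, whose exchange-broadened shifts are
unreliable; they still participate in assignment, they are just never
written to the database.

## Numerical choices

* Integral rounding is half-away-from-zero, not banker's rounding, so
  `x.5` cases resolve the same way on every platform.
* The assignment tolerance is floored at 0.02 ppm: duplicate
  observations give $\varepsilon = 0$, and a zero window would lock out
  every peak and deadlock the loop.
* Solutions are reported sorted lexicographically by peak index in
  class order, and ties in the most-constrained branching order fall
  back to class index, so every enumeration is fully deterministic.
* The median of an even match count is the mean of the two central
  values; repeated queries of an unchanged database are byte-identical.
* Failure to predict is a status, not an exception; infeasible and
  overflowed molecules are counted in the iteration report, never
  fatal.

## The synthetic corpus

Real training corpora are thousands of proprietary spectra; the package
instead ships a generator whose output has exactly the statistical
structure the loop assumes. Molecules grow from a small grammar (alkyl
chains and benzene rings decorated with methyl, hydroxyl, amino,
methoxy, chloro and carbonyl groups; 2–9 heavy atoms), which produces
the features that matter — symmetric methyls, aromatic equivalence,
heteroatom environments — at desk scale. Ground truth is a *radius-2
rule*: every distinct radius-2 code in the corpus is assigned a base
shift on an even grid over 0.5–11.5 ppm (seeded random order), and a
class's true shift is its base shift plus Gaussian noise of
$\sigma = 0.05$ ppm, drawn once per class per molecule so that
equivalent protons share one signal. Peaks closer than 0.02 ppm merge
at the integral-weighted mean. Because the truth is a function of the
radius-2 environment, a predictor with $n_\min = 2$ is asymptotically
unbiased on this corpus and "error converges to the noise floor" is a
meaningful recovery target; the benchmark in the suite trains on 150
molecules, holds out 30, and asserts final MAE ≤ 0.10 ppm (twice the
noise), no regression from iteration 0, and non-decreasing radius-4
coverage. Those sizes keep the full loop in a few seconds while leaving
~40 distinct environments to learn.

What the synthetic corpus does **not** emulate: multiplet structure and
scalar couplings, lineshapes, solvent/temperature/concentration
effects, labile-proton exchange, and the long-tailed environment
distribution of real chemical libraries. Passing the recovery benchmark
shows the loop's mechanics (consensus harvesting, batch updates,
cascade lookup, tolerance scaling) are sound, not that real-world
accuracy figures transfer; on experimental corpora the irreducible
spread of shifts within one radius-2 environment is far larger than
0.05 ppm. A single corpus draw is one realisation of a stochastic
generator: the across-seed spread of the test-set MAE is a few
thousandths of a ppm, so iteration-over-iteration improvement holds in
the mean but an individual run may fluctuate at that scale.

## A worked run

```{r run}
corpus <- syntheticCorpus(seed = 1)
out <- train(corpus$train, learnerConfig(), testSet = corpus$test)
out$reports[, c("iteration", "solved", "newEntries", "dbSize",
                "eval.coverage", "eval.mae", "eval.coverageR4")]
```

The database grows monotonically, learning stops when two consecutive
passes add nothing, coverage and radius-4 coverage rise, and the MAE
settles near the 0.05 ppm noise floor.

## Limitations

* Constitution-only codes: diastereotopic and stereo-dependent shifts
  are out of reach by construction.
* Underrepresented environments stay wrong: a code observed once keeps
  a 20 ppm window forever and can never self-correct — the dominant
  error source for this class of method.
* Aromaticity is trusted from the input file (bond type 4); Kekulé
  inputs are not re-perceived, and five-membered heteroaromatics are
  outside the hydrogen-completion rules.
* The assigner uses integrals and shifts only; 2D correlation data and
  multiplet structure, which would prune far harder, are not modelled.
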