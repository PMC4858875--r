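# hoseNMR

Self-learning 1H NMR chemical shift prediction and assignment for small
molecules — an R implementation of the assignment–prediction bootstrap:
a HOSE-code nearest-fragment shift predictor and an integral/shift-
constrained combinatorial assigner are iterated against a corpus of
*unassigned* spectra, so the prediction database is built entirely from
the spectra themselves, with no human-assigned training data.

**Who it is for.** Cheminformatics and NMR-automation developers who
need a transparent, dependency-light reference implementation of
HOSE-based 1H prediction, symmetry-aware assignment enumeration, and
the self-training loop that couples them — plus a synthetic benchmark
generator for studying the loop's behaviour at desk scale.

## The method

* **Prediction.** Every database entry is a (fragment, shift) pair, the
  fragment being the *n*-sphere of a proton (all atoms within *n*
  bonds) serialised as a canonical HOSE code. A query cascades from
  radius *n*max = 4 down to *n*min = 2; the first radius with matches
  returns the median shift δ̄ with uncertainty ε = the sample standard
  deviation of the matches, or a failed status below *n*min.
* **Assignment.** Proton equivalence classes (graph-automorphism
  orbits of the hydrogens) are mapped to peaks by branch-and-bound so
  that integer-rounded integrals balance exactly per peak and, when a
  prediction exists, the peak lies within `3·ε·(1 + m^(−I/2))` ppm of
  the predicted shift (*m* = match count, *I* = iteration; below two
  matches the window is 20 ppm).
* **Learning.** Class→peak pairs present in *every* enumerated solution
  of a molecule ("consensus dyads") are committed to the database at
  radii 2–4, in one batch at the end of each iteration. Iteration 0
  uses integrals only; the loop stops when two consecutive iterations
  learn nothing new, or after 10 iterations.

## Worked example

The package's built-in worked example is a five-proton molecule with
five unit-integral peaks in which two pairs of protons are mutually
interchangeable and one proton is pinned:

```r
library(hoseNMR)
ex <- fiveProtonExample()
sols <- enumerateAssignments(ex)
solutionMatrix(sols)
#>      a b c d e
#> [1,] 1 2 3 4 5
#> [2,] 1 2 3 5 4
#> [3,] 2 1 3 4 5
#> [4,] 2 1 3 5 4
consensusDyads(sols)
#>   class peak delta
#> 1     3    3  4.16
```

Four feasible assignments exist (a/b swap over the 1.30/2.52 ppm
peaks, d/e over 7.47/8.27 ppm), but class **c** sits on the 4.16 ppm
peak in all of them — that single invariant pair is what the learner
commits to its database.

A full self-learning run on the bundled synthetic benchmark (150
training molecules, 30 held out, 0.05 ppm observation noise):

```r
corpus <- syntheticCorpus(seed = 1)
out <- train(corpus$train, learnerConfig(), testSet = corpus$test)
out$reports[, c("iteration", "solved", "newEntries", "dbSize",
                "eval.coverage", "eval.mae", "eval.coverageR4")]
#>   iteration solved newEntries dbSize eval.coverage   eval.mae eval.coverageR4
#> 1         0    150        675    675     0.7560976 0.05041481       0.3048780
#> 2         1    136        321    996     0.8414634 0.04530410       0.3658537
#> 3         2    141         81   1077     0.8414634 0.04473379       0.4146341
#> 4         3    146         30   1107     0.8414634 0.04473370       0.4146341
#> 5         4    146          3   1110     0.8414634 0.04477158       0.4146341
#> 6         5    146          0   1110     0.8414634 0.04477158       0.4146341
#> 7         6    146          0   1110     0.8414634 0.04477158       0.4146341
```

Reading the table: the database only ever grows; iteration 0 already
resolves the molecules whose integrals are unambiguous; later
iterations use learnt shift windows to resolve more (`solved` rises,
and the share of predictions made at the most specific radius,
`eval.coverageR4`, climbs from 30 % to 41 %); the held-out mean
absolute error drops from 0.0504 to 0.0448 ppm, at the 0.05 ppm noise
floor of the generator; and the loop stops itself after two passes
that learn nothing.

Command-line wrappers over the same functions (`synth.R`, `train.R`,
`predict.R`, `assign.R`) live in `inst/cli/`, and
`inst/scripts/external-benchmark.R` runs the corpus-scale experiment if
you supply your own SDF + peak-list dataset. See the vignette in
`vignettes/` for the model, its assumptions and the design decisions.

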