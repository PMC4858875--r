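#' Generate a deterministic corpus of small molecules
#'
#' Grows molecules from a small fragment grammar: an alkyl-chain or
#' benzene-ring scaffold decorated with methyl, hydroxyl, amino, methoxy,
#' chloro and carbonyl substituents until a target heavy-atom count is
#' reached, then completes hydrogens. The grammar covers the feature mix
#' the learning loop must cope with — symmetric methyls, aromatic rings,
#' heteroatom neighbours, overlapping equivalence classes — while keeping
#' every molecule small enough for exhaustive reasoning.
#'
#' @param count number of molecules, >= 1.
#' @param seed integer seed; the output is byte-identical across runs for
#'   a fixed seed and the caller's RNG state is left untouched.
#' @param heavyAtomRange integer length-2, inclusive bounds on heavy-atom
#'   counts.
#' @param idPrefix prefix for record identifiers (`<prefix>0001`, ...).
#' @return list of hydrogen-complete, connected [Molecule-class] objects,
#'   each with at least one proton.
#' @examples
#' mols <- genMolecules(3, seed = 1)
#' vapply(mols, molId, character(1))
#' @export
genMolecules <- function(count, seed, heavyAtomRange = c(2L, 9L),
                         idPrefix = "SYN") {
  stopifnot(count >= 1L, length(heavyAtomRange) == 2L,
            heavyAtomRange[1L] >= 1L,
            heavyAtomRange[1L] <= heavyAtomRange[2L])
  withSeed(seed, {
    lapply(seq_len(count), function(i) {
      genOneMolecule(heavyAtomRange, sprintf("%s%04d", idPrefix, i))
    })
  })
}

# One molecule from the grammar; retries until it carries a proton.
genOneMolecule <- function(heavyAtomRange, id) {
  repeat {
    target <- sample(seq.int(heavyAtomRange[1L], heavyAtomRange[2L]), 1L)
    useRing <- target >= 6L && stats::runif(1) < 0.4
    if (useRing) {
      symbols <- rep("C", 6L)
      bonds <- data.frame(from = 1:6, to = c(2:6, 1L), order = 4L)
      freeVal <- rep(1L, 6L)           # one substituent slot per ring C
      aromatic <- rep(TRUE, 6L)
    } else {
      len <- min(target, sample(1:5, 1L))
      symbols <- rep("C", len)
      bonds <- if (len > 1L)
        data.frame(from = seq_len(len - 1L), to = 2:len, order = 1L)
      else data.frame(from = integer(0), to = integer(0), order = integer(0))
      deg <- tabulate(c(bonds$from, bonds$to), len)
      freeVal <- 4L - deg
      aromatic <- rep(FALSE, len)
    }
    # grow substituents until the heavy-atom budget is spent
    while (length(symbols) < target) {
      budget <- target - length(symbols)
      sites <- which(freeVal >= 1L & symbols == "C")
      if (length(sites) == 0L) break
      at <- if (length(sites) == 1L) sites else sample(sites, 1L)
      opts <- c("methyl", "hydroxyl", "amino", "chloro")
      if (budget >= 2L) opts <- c(opts, "methoxy")
      if (!aromatic[at] && freeVal[at] >= 2L) opts <- c(opts, "carbonyl")
      grp <- if (length(opts) == 1L) opts else sample(opts, 1L)
      addAtom <- function(sym, order) {
        symbols <<- c(symbols, sym)
        bonds <<- rbind(bonds, data.frame(from = at, to = length(symbols),
                                          order = order))
        aromatic <<- c(aromatic, FALSE)
        length(symbols)
      }
      if (grp == "methyl") {
        j <- addAtom("C", 1L); freeVal <- c(freeVal, 3L)
        freeVal[at] <- freeVal[at] - 1L
      } else if (grp == "hydroxyl") {
        j <- addAtom("O", 1L); freeVal <- c(freeVal, 0L)
        freeVal[at] <- freeVal[at] - 1L
      } else if (grp == "amino") {
        j <- addAtom("N", 1L); freeVal <- c(freeVal, 0L)
        freeVal[at] <- freeVal[at] - 1L
      } else if (grp == "chloro") {
        j <- addAtom("Cl", 1L); freeVal <- c(freeVal, 0L)
        freeVal[at] <- freeVal[at] - 1L
      } else if (grp == "methoxy") {
        j <- addAtom("O", 1L); freeVal <- c(freeVal, 1L)
        freeVal[at] <- freeVal[at] - 1L
        at <- j
        j <- addAtom("C", 1L); freeVal <- c(freeVal, 3L)
        freeVal[at] <- freeVal[at] - 1L
      } else if (grp == "carbonyl") {
        j <- addAtom("O", 2L); freeVal <- c(freeVal, 0L)
        freeVal[at] <- freeVal[at] - 2L
      }
    }
    mol <- completeHydrogens(molecule(symbols, bonds, id = id))
    if (sum(isHydrogen(mol)) >= 1L) return(mol)
  }
}

#' A ground-truth shift rule over radius-2 environments
#'
#' Builds the "nature" of a synthetic experiment: a lookup from radius-2
#' HOSE codes to base chemical shifts. All distinct radius-2 codes found
#' in the corpus are mapped to shifts spread evenly over `shiftRange`
#' (assigned in seeded random order), so environments are well separated;
#' per-molecule observations add Gaussian noise of `sigma` ppm. Because
#' the truth is a function of the radius-2 environment, a predictor with
#' `rMin = 2` is asymptotically unbiased on this corpus and the noise
#' floor is a meaningful convergence target.
#'
#' @param mols list of hydrogen-complete [Molecule-class] objects.
#' @param seed integer seed for the code-to-shift permutation.
#' @param sigma noise standard deviation in ppm, >= 0.
#' @param shiftRange numeric length-2, ppm range for base shifts.
#' @param fallback base shift (ppm) for codes outside the corpus.
#' @return list with class `"ShiftRule"`: `lookup` (named numeric),
#'   `sigma`, `fallback`.
#' @export
makeShiftRule <- function(mols, seed, sigma = 0.05,
                          shiftRange = c(0.5, 11.5), fallback = 5.0) {
  stopifnot(sigma >= 0, length(shiftRange) == 2L)
  codes <- unique(unlist(lapply(mols, function(mol) {
    classes <- protonClasses(mol)
    vapply(classes, function(cl) hoseCode(mol, cl[[1L]], 2L), character(1))
  })))
  codes <- sort(codes)
  n <- length(codes)
  base <- if (n == 1L) mean(shiftRange)
          else seq(shiftRange[1L], shiftRange[2L], length.out = n)
  base <- withSeed(seed, base[sample.int(n)])
  names(base) <- codes
  structure(list(lookup = base, sigma = sigma, fallback = fallback),
            class = "ShiftRule")
}

#' True dyads of a molecule under a shift rule
#'
#' One noise draw per equivalence class per molecule (not per proton):
#' equivalent protons share one observed signal, so they must share one
#' true shift. Draws use the current RNG state; wrap in a seeded context
#' (or pass `seed`) for reproducibility.
#'
#' @param rule a `"ShiftRule"` from [makeShiftRule()].
#' @param mol a hydrogen-complete [Molecule-class].
#' @param classes optional pre-computed [protonClasses()] result.
#' @param seed optional integer seed for the noise draws.
#' @return data.frame with columns `class` (index), `size`,
#'   `representative` (a proton atom index) and `delta` (true shift, ppm).
#' @export
applyShiftRule <- function(rule, mol, classes = NULL, seed = NULL) {
  stopifnot(inherits(rule, "ShiftRule"))
  if (is.null(classes)) classes <- protonClasses(mol)
  body <- function() {
    k <- length(classes)
    reps <- vapply(classes, function(cl) cl[[1L]], integer(1))
    codes <- vapply(reps, function(p) hoseCode(mol, p, 2L), character(1))
    base <- unname(rule$lookup[codes])
    base[is.na(base)] <- rule$fallback
    noise <- if (rule$sigma > 0) stats::rnorm(k, 0, rule$sigma) else numeric(k)
    data.frame(class = seq_len(k), size = lengths(classes),
               representative = reps, delta = base + noise)
  }
  if (is.null(seed)) body() else withSeed(seed, body())
}

#' Simulate a peak list from true dyads
#'
#' Dyads whose shifts lie within `mergeWidth` of each other (single
#' linkage on the sorted shifts) merge into one peak at the
#' integral-weighted mean position; integrals are the summed class sizes,
#' so the total peak integral always equals the proton count.
#'
#' @param dyads data.frame as returned by [applyShiftRule()].
#' @param mergeWidth merge width in ppm; 0 never merges.
#' @return data.frame with columns `position` and `integral`, sorted by
#'   position.
#' @examples
#' d <- data.frame(class = 1:2, size = c(1, 1),
#'                 representative = c(1, 2), delta = c(7.20, 7.21))
#' simulatePeaks(d, mergeWidth = 0.02)  # one peak at 7.205, integral 2
#' @export
simulatePeaks <- function(dyads, mergeWidth = 0.02) {
  stopifnot(nrow(dyads) >= 1L, mergeWidth >= 0)
  o <- order(dyads$delta)
  delta <- dyads$delta[o]; size <- dyads$size[o]
  groups <- cumsum(c(1, diff(delta) > mergeWidth))
  position <- as.numeric(tapply(delta * size, groups, sum) /
                           tapply(size, groups, sum))
  integral <- as.numeric(tapply(size, groups, sum))
  data.frame(position = position, integral = integral)
}

#' Generate a complete synthetic training/test corpus
#'
#' Generates molecules, derives the ground-truth shift rule from the full
#' corpus, draws per-molecule true dyads, and simulates peak lists for
#' the training records and reference assignments for the test records.
#' Everything is deterministic for a fixed `seed`.
#'
#' @param seed integer seed.
#' @param nTrain,nTest corpus sizes (defaults 150 and 30).
#' @param sigma observation noise in ppm (default 0.05).
#' @param heavyAtomRange heavy-atom bounds for [genMolecules()].
#' @param config a [learnerConfig()] list (supplies `mergeWidth`).
#' @return list with `train` (records with `molecule`, `peaks`,
#'   `trueDyads`), `test` (records with `molecule`, `peaks`, `reference`)
#'   and `rule` (the `"ShiftRule"`).
#' @export
syntheticCorpus <- function(seed, nTrain = 150L, nTest = 30L, sigma = 0.05,
                            heavyAtomRange = c(2L, 9L),
                            config = learnerConfig()) {
  mols <- genMolecules(nTrain + nTest, seed, heavyAtomRange)
  rule <- makeShiftRule(mols, seed + 1L, sigma)
  records <- withSeed(seed + 2L, lapply(mols, function(mol) {
    classes <- protonClasses(mol)
    dyads <- applyShiftRule(rule, mol, classes = classes)
    peaks <- simulatePeaks(dyads, config$mergeWidth)
    list(molecule = mol, peaks = peaks, trueDyads = dyads,
         reference = data.frame(atom_index = dyads$representative,
                                delta_ppm = dyads$delta))
  }))
  list(train = lapply(records[seq_len(nTrain)],
                      function(r) r[c("molecule", "peaks", "trueDyads")]),
       test = records[nTrain + seq_len(nTest)],
       rule = rule)
}

#' Write a synthetic corpus to disk
#'
#' Emits the same formats the main pipeline reads: `train.sdf` and
#' `test.sdf`, one peak-list TSV per molecule under `peaks/`, and the
#' test reference table `reference.tsv`.
#'
#' @param corpus a list from [syntheticCorpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  writeSDF(lapply(corpus$train, `[[`, "molecule"),
           file.path(dir, "train.sdf"))
  writeSDF(lapply(corpus$test, `[[`, "molecule"),
           file.path(dir, "test.sdf"))
  for (rec in c(corpus$train, corpus$test))
    writePeakList(rec$peaks,
                  file.path(dir, "peaks",
                            paste0(molId(rec$molecule), ".tsv")))
  refs <- do.call(rbind, lapply(corpus$test, function(rec)
    data.frame(molecule_id = molId(rec$molecule),
               atom_index = rec$reference$atom_index,
               delta_ppm = rec$reference$delta_ppm)))
  writeReferenceShifts(refs, file.path(dir, "reference.tsv"))
  invisible(dir)
}
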