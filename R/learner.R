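#' Configuration of the self-learning loop
#'
#' @param rMin,rMax sphere radius range for database entries and cascade
#'   lookup (defaults 2 and 4).
#' @param maxIterations iteration cap (default 10; iterations are indexed
#'   0 .. maxIterations-1).
#' @param lowMatchThreshold predictions with fewer matches than this get
#'   the `maxTolerance` fallback window. Default 2; set to 3 for the
#'   stricter variant that also distrusts two-match predictions.
#' @param solutionCap abort enumeration beyond this many solutions.
#' @param toleranceFloor lower bound (ppm) on the assignment tolerance, so
#'   that duplicate observations (epsilon 0) cannot lock out every
#'   assignment.
#' @param maxTolerance fallback window (ppm) for low-match predictions.
#' @param mergeWidth peak-merging width (ppm) used by the synthetic
#'   spectrum simulator.
#' @param excludeLabile if TRUE, dyads whose protons sit on O, N or S
#'   (exchangeable protons with environment-dependent shifts) are never
#'   committed to the database.
#' @param seed optional integer seed for synthetic runs.
#' @return a validated list with class `"LearnerConfig"`.
#' @export
learnerConfig <- function(rMin = 2L, rMax = 4L, maxIterations = 10L,
                          lowMatchThreshold = 2L, solutionCap = 10000L,
                          toleranceFloor = 0.02, maxTolerance = 20,
                          mergeWidth = 0.02, excludeLabile = FALSE,
                          seed = NULL) {
  stopifnot(rMin >= 1L, rMin <= rMax, maxIterations >= 1L,
            solutionCap >= 1L, toleranceFloor >= 0, maxTolerance > 0)
  structure(list(rMin = as.integer(rMin), rMax = as.integer(rMax),
                 maxIterations = as.integer(maxIterations),
                 lowMatchThreshold = as.integer(lowMatchThreshold),
                 solutionCap = as.integer(solutionCap),
                 toleranceFloor = toleranceFloor,
                 maxTolerance = maxTolerance,
                 mergeWidth = mergeWidth,
                 excludeLabile = isTRUE(excludeLabile),
                 seed = seed),
            class = "LearnerConfig")
}

#' Prepare a training/test record for repeated use
#'
#' Precomputes the proton equivalence classes, one representative proton
#' per class, the representative's HOSE codes at every radius, and a
#' labile flag (proton bonded to O/N/S). Records prepared once are reused
#' across all iterations, since codes depend only on the molecule.
#'
#' @param mol a hydrogen-complete [Molecule-class].
#' @param peaks data.frame with columns `position`, `integral` (may be
#'   `NULL` for pure test molecules).
#' @param config a [learnerConfig()] list.
#' @return list with elements `molecule`, `peaks`, `classes`,
#'   `representatives`, `codes` (list of named code vectors, one per
#'   class), `labile` (logical per class).
#' @export
prepareRecord <- function(mol, peaks = NULL, config = learnerConfig()) {
  stopifnot(is(mol, "Molecule"))
  classes <- protonClasses(mol)
  reps <- vapply(classes, function(cl) cl[[1L]], integer(1))
  adj <- adjacencyList(mol)
  codes <- lapply(reps, function(p) {
    radii <- seq.int(config$rMin, config$rMax)
    out <- vapply(radii, function(r) encodeFromAdjacency(mol, adj, p, r),
                  character(1))
    names(out) <- radii
    out
  })
  labile <- vapply(reps, function(p) {
    nb <- adj[[p]][, 1L]
    any(mol@atoms$symbol[nb] %in% c("O", "N", "S"))
  }, logical(1))
  list(molecule = mol, peaks = peaks, classes = classes,
       representatives = reps, codes = codes, labile = labile)
}

#' Run one learning iteration against a frozen database
#'
#' Every molecule of the training set is assigned against the database as
#' it stood at the start of the iteration; consensus dyads from all
#' molecules are collected and committed in one batch at the end
#' ("chemical shifts learnt in one cycle are only available starting from
#' the next one"). At iteration 0 no shift constraints are used at all.
#' Infeasible problems and overflowed enumerations are counted and
#' skipped, never fatal.
#'
#' @param db the [ShiftDatabase-class] at the start of the iteration.
#' @param records list of prepared records ([prepareRecord()]); entries
#'   lacking `$classes` are prepared on the fly.
#' @param I iteration index (0 = unconstrained first pass).
#' @param config a [learnerConfig()] list.
#' @return list with `db` (the batch-updated database) and `report`, a
#'   one-row data.frame: iteration, attempted, solved, overflowed,
#'   infeasible, newEntries, dbSize.
#' @export
runIteration <- function(db, records, I, config = learnerConfig()) {
  stopifnot(is(db, "ShiftDatabase"), I >= 0L)
  attempted <- solved <- overflowed <- infeasible <- 0L
  harvest <- vector("list", length(records))
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    if (is.null(rec$classes))
      rec <- prepareRecord(rec$molecule, rec$peaks, config)
    attempted <- attempted + 1L
    preds <- NULL
    if (I > 0L && nEntries(db) > 0L)
      preds <- lapply(rec$codes, function(cd) predictShift(db, codes = cd))
    problem <- tryCatch(
      buildProblem(rec$molecule, rec$peaks, predictions = preds, I = I,
                   config = config, classes = rec$classes),
      hoseNMR_infeasible = function(e) NULL)
    if (is.null(problem)) { infeasible <- infeasible + 1L; next }
    sols <- enumerateAssignments(problem, cap = config$solutionCap)
    if (sols@status == "overflow") { overflowed <- overflowed + 1L; next }
    if (nrow(sols@solutions) == 0L) next
    solved <- solved + 1L
    cons <- consensusDyads(sols)
    if (nrow(cons) == 0L) next
    rows <- lapply(seq_len(nrow(cons)), function(j) {
      cl <- cons$class[j]
      if (config$excludeLabile && rec$labile[cl]) return(NULL)
      cd <- rec$codes[[cl]]
      data.frame(code = unname(cd), radius = as.integer(names(cd)),
                 delta = cons$delta[j], moleculeId = molId(rec$molecule),
                 iteration = as.integer(I), stringsAsFactors = FALSE)
    })
    harvest[[ri]] <- do.call(rbind, rows)
  }
  before <- nEntries(db)
  newDb <- addEntries(db, do.call(rbind, harvest))
  report <- data.frame(iteration = as.integer(I), attempted = attempted,
                       solved = solved, overflowed = overflowed,
                       infeasible = infeasible,
                       newEntries = nEntries(newDb) - before,
                       dbSize = nEntries(newDb))
  list(db = newDb, report = report)
}

#' Train the self-learning loop
#'
#' Runs iterations starting at 0 (integral constraints only) and then
#' constrained iterations, committing batch updates after each pass.
#' Learning stops when two consecutive iterations add zero new database
#' entries, or at the iteration cap. When a test set is supplied, the
#' end-of-iteration database is evaluated after every pass and the
#' metrics are appended to that iteration's report row.
#'
#' @param records training set: list of records, each a list with
#'   `molecule` (hydrogen-complete [Molecule-class]) and `peaks`
#'   (data.frame `position`, `integral`), or already prepared via
#'   [prepareRecord()].
#' @param config a [learnerConfig()] list.
#' @param testSet optional list of test records, each with `molecule` and
#'   `reference` (data.frame `atom_index`, `delta_ppm`).
#' @return list with `db` (final [ShiftDatabase-class]) and `reports`
#'   (data.frame, one row per iteration; evaluation columns prefixed
#'   `eval.` when a test set was given).
#' @export
train <- function(records, config = learnerConfig(), testSet = NULL) {
  records <- lapply(records, function(rec) {
    if (is.null(rec$classes)) prepareRecord(rec$molecule, rec$peaks, config)
    else rec
  })
  if (!is.null(testSet))
    testSet <- lapply(testSet, function(rec) {
      if (is.null(rec$classes)) {
        p <- prepareRecord(rec$molecule, rec$peaks, config)
        p$reference <- rec$reference
        p
      } else rec
    })
  db <- shiftDatabase(config$rMin, config$rMax)
  reports <- list()
  zeroStreak <- 0L
  for (I in seq_len(config$maxIterations) - 1L) {
    step <- runIteration(db, records, I, config)
    db <- step$db
    rep_ <- step$report
    if (!is.null(testSet)) {
      ev <- evaluate(db, testSet, config)
      evRow <- as.data.frame(ev[c("nReference", "nPredicted", "coverage",
                                  "mae", "fracWithin02", "fracAbove1",
                                  "meanEpsilon")])
      for (r in seq.int(config$rMin, config$rMax))
        evRow[[paste0("coverageR", r)]] <- ev$coverageByRadius[[as.character(r)]]
      names(evRow) <- paste0("eval.", names(evRow))
      rep_ <- cbind(rep_, evRow)
    }
    reports[[length(reports) + 1L]] <- rep_
    zeroStreak <- if (rep_$newEntries == 0L) zeroStreak + 1L else 0L
    if (zeroStreak >= 2L) break
  }
  list(db = db, reports = do.call(rbind, reports))
}

#' Evaluate predictions against reference assignments
#'
#' For every reference proton the shift is predicted from the database;
#' absolute errors are computed over successful predictions only, while
#' failed predictions count against coverage. The mean absolute error of
#' an empty prediction set is reported as `NA`, never 0.
#'
#' @param db a [ShiftDatabase-class].
#' @param testSet list of records with `molecule` and `reference`
#'   (data.frame `atom_index`, `delta_ppm`); prepared records are reused.
#' @param config a [learnerConfig()] list.
#' @return list with `nReference`, `nPredicted`, `coverage`,
#'   `coverageByRadius` (named by radius; sums to `coverage`), `mae`,
#'   `fracWithin02` (fraction of predicted protons with error < 0.2 ppm),
#'   `fracAbove1` (error > 1 ppm), `meanEpsilon` (mean uncertainty over
#'   predictions with at least two matches) and `errors` (the per-proton
#'   absolute errors).
#' @export
evaluate <- function(db, testSet, config = learnerConfig()) {
  stopifnot(is(db, "ShiftDatabase"))
  radii <- as.character(seq.int(config$rMin, config$rMax))
  errors <- numeric(0)
  epsilons <- numeric(0)
  usedRadius <- integer(0)
  nRef <- 0L
  for (rec in testSet) {
    if (is.null(rec$classes)) {
      p <- prepareRecord(rec$molecule, rec$peaks, config)
      p$reference <- rec$reference
      rec <- p
    }
    ref <- rec$reference
    if (is.null(ref) || nrow(ref) == 0L) next
    # map each reference proton to its equivalence class
    classOf <- integer(atomCount(rec$molecule))
    for (ci in seq_along(rec$classes)) classOf[rec$classes[[ci]]] <- ci
    for (j in seq_len(nrow(ref))) {
      nRef <- nRef + 1L
      ci <- classOf[ref$atom_index[j]]
      if (ci == 0L)
        stop("reference atom ", ref$atom_index[j], " is not a proton of '",
             molId(rec$molecule), "'", call. = FALSE)
      pred <- predictShift(db, codes = rec$codes[[ci]])
      if (pred@status == "ok") {
        errors <- c(errors, abs(pred@delta - ref$delta_ppm[j]))
        usedRadius <- c(usedRadius, pred@radiusUsed)
        if (!is.na(pred@epsilon)) epsilons <- c(epsilons, pred@epsilon)
      }
    }
  }
  nPred <- length(errors)
  covByR <- vapply(radii, function(r) {
    if (nRef == 0L) 0 else sum(usedRadius == as.integer(r)) / nRef
  }, numeric(1))
  list(nReference = nRef,
       nPredicted = nPred,
       coverage = if (nRef == 0L) 0 else nPred / nRef,
       coverageByRadius = covByR,
       mae = if (nPred == 0L) NA_real_ else mean(errors),
       fracWithin02 = if (nPred == 0L) NA_real_ else mean(errors < 0.2),
       fracAbove1 = if (nPred == 0L) NA_real_ else mean(errors > 1),
       meanEpsilon = if (length(epsilons) == 0L) NA_real_ else mean(epsilons),
       errors = errors)
}

#' Binned cumulative error distribution
#'
#' Splits the prediction errors into 100 bins of `binWidth` ppm plus one
#' last bin holding all errors at or above `nBins * binWidth` (1 ppm at
#' the defaults), and reports the cumulative fraction of predictions up
#' to each bin's upper edge. The curve is monotone non-decreasing and
#' ends at 1.
#'
#' @param errors non-negative prediction errors (ppm).
#' @param binWidth bin width in ppm (default 0.01).
#' @param nBins number of regular bins before the catch-all (default 100).
#' @return data.frame with columns `upper` (bin upper edge; `Inf` for the
#'   last bin) and `cumulative` (fraction of all errors below `upper`).
#'   For empty input all fractions are 0 and the attribute `empty` is set.
#' @examples
#' errorCdf(c(0.005, 0.5, 1.5))$cumulative[c(1, 101)]  # 1/3, 1
#' @export
errorCdf <- function(errors, binWidth = 0.01, nBins = 100L) {
  stopifnot(all(errors >= 0))
  upper <- c(seq_len(nBins) * binWidth, Inf)
  n <- length(errors)
  cum <- if (n == 0L) rep(0, nBins + 1L)
         else vapply(upper, function(u) sum(errors < u) / n, numeric(1))
  out <- data.frame(upper = upper, cumulative = cum)
  attr(out, "empty") <- n == 0L
  out
}

#' Serialize iteration reports to and from JSON
#'
#' One JSON object per iteration row; the round trip is lossless.
#'
#' @param reports data.frame of iteration reports (from [train()]).
#' @param path file path.
#' @return `writeReports`: `path` invisibly; `readReports`: the
#'   data.frame.
#' @export
writeReports <- function(reports, path) {
  jsonlite::write_json(reports, path, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReports
#' @export
readReports <- function(path) {
  out <- jsonlite::fromJSON(path)
  out$iteration <- as.integer(out$iteration)
  out
}
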