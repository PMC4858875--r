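#' Build an assignment problem from a molecule and a peak list
#'
#' Raw integrals are in arbitrary units; they are rescaled so their sum
#' equals the molecule's proton count and then rounded half-away-from-zero
#' to integers. A problem whose rounded integrals do not sum to the proton
#' count is infeasible (condition class `"hoseNMR_infeasible"`): the
#' molecule is skipped by the learner. When predictions are supplied
#' (iterations after the first), each successfully predicted class gets a
#' shift window of [assignmentTolerance()] ppm around the predicted shift;
#' failed predictions leave the class unconstrained.
#'
#' @param mol a hydrogen-complete [Molecule-class].
#' @param peaks data.frame with columns `position` (ppm) and `integral`.
#' @param predictions optional list of [ShiftPrediction-class] objects,
#'   one per proton class (in [protonClasses()] order); `NULL` entries or
#'   a `NULL` list mean no shift constraints (iteration 0).
#' @param I iteration index, used to scale tolerances.
#' @param config a [learnerConfig()] list.
#' @param classes optional pre-computed [protonClasses()] result.
#' @return an [AssignmentProblem-class].
#' @examples
#' eth <- completeHydrogens(molecule(c("C", "C", "O"),
#'   data.frame(from = c(1, 2), to = c(2, 3), order = 1), id = "ethanol"))
#' pk <- data.frame(position = c(1.2, 3.7, 2.6), integral = c(3.1, 2.0, 0.9))
#' buildProblem(eth, pk)
#' @export
buildProblem <- function(mol, peaks, predictions = NULL, I = 0L,
                         config = learnerConfig(), classes = NULL) {
  stopifnot(is(mol, "Molecule"), nrow(peaks) >= 1L)
  if (is.null(classes)) classes <- protonClasses(mol)
  if (length(classes) == 0L)
    stop("molecule has no protons", call. = FALSE)
  sizes <- lengths(classes)
  nH <- sum(sizes)
  scale <- nH / sum(peaks$integral)
  intInt <- as.integer(roundHalfAway(peaks$integral * scale))
  if (sum(intInt) != nH) {
    cond <- structure(
      class = c("hoseNMR_infeasible", "error", "condition"),
      list(message = sprintf(
             "molecule '%s': rounded integrals sum to %d, expected %d protons",
             molId(mol), sum(intInt), nH),
           call = NULL))
    stop(cond)
  }
  k <- length(sizes)
  centers <- rep(NA_real_, k); tols <- rep(NA_real_, k)
  if (!is.null(predictions)) {
    stopifnot(length(predictions) == k)
    for (i in seq_len(k)) {
      p <- predictions[[i]]
      if (!is.null(p) && is(p, "ShiftPrediction") && p@status == "ok") {
        centers[i] <- p@delta
        tols[i] <- assignmentTolerance(p, I, config)
      }
    }
  }
  new("AssignmentProblem",
      classSizes = as.integer(sizes),
      classLabels = paste0("class", seq_len(k)),
      peaks = data.frame(position = peaks$position,
                         integral = peaks$integral,
                         integerIntegral = intInt),
      centers = centers, tolerances = tols, moleculeId = molId(mol))
}

#' Construct an assignment problem directly from sizes and peaks
#'
#' Low-level companion of [buildProblem()] for worked examples and tests:
#' class sizes and integer integrals are given directly, with optional
#' per-class shift windows.
#'
#' @param classSizes integer vector of proton-class sizes.
#' @param positions peak positions (ppm).
#' @param integrals integer peak integrals.
#' @param centers,tolerances optional per-class window centre/half-width
#'   (ppm); `NA` centre = unconstrained class.
#' @param labels optional class labels.
#' @param id problem identifier.
#' @return an [AssignmentProblem-class].
#' @export
assignmentProblem <- function(classSizes, positions, integrals,
                              centers = rep(NA_real_, length(classSizes)),
                              tolerances = rep(NA_real_, length(classSizes)),
                              labels = paste0("class", seq_along(classSizes)),
                              id = "problem") {
  new("AssignmentProblem",
      classSizes = as.integer(classSizes), classLabels = labels,
      peaks = data.frame(position = positions, integral = integrals,
                         integerIntegral = as.integer(integrals)),
      centers = as.numeric(centers), tolerances = as.numeric(tolerances),
      moleculeId = id)
}

#' Enumerate all assignments consistent with integrals and shift windows
#'
#' Performs a symmetry-constrained branch-and-bound search over proton
#' equivalence classes (never individual protons): each class is placed on
#' a peak whose remaining integer integral can absorb the class size and,
#' when the class carries a shift window, whose position lies within the
#' window (closed interval). A solution must balance every peak exactly —
#' the class sizes mapped to each peak sum to its integer integral — so
#' several classes may share one peak (overlapping signals). Classes are
#' branched most-constrained-first (fewest feasible peaks), which affects
#' only speed, never the solution set. Enumeration aborts with status
#' `"overflow"` when more than `cap` solutions exist; nothing may be
#' learnt from such a molecule.
#'
#' @param problem an [AssignmentProblem-class].
#' @param cap maximum number of solutions before aborting.
#' @return an [AssignmentSet-class]; solutions are rows of peak indices in
#'   problem class order, sorted lexicographically.
#' @examples
#' pr <- assignmentProblem(c(3, 2, 1), c(1.2, 3.7, 2.6), c(3, 1, 2))
#' solutionMatrix(enumerateAssignments(pr))
#' @export
enumerateAssignments <- function(problem, cap = 10000L) {
  stopifnot(is(problem, "AssignmentProblem"))
  sizes <- problem@classSizes
  k <- length(sizes)
  pos <- problem@peaks$position
  caps <- problem@peaks$integerIntegral
  nP <- length(pos)

  # feasible peak sets per class (capacity + shift window)
  feas <- lapply(seq_len(k), function(i) {
    ok <- caps >= sizes[i]
    if (!is.na(problem@centers[i]))
      ok <- ok & abs(pos - problem@centers[i]) <= problem@tolerances[i]
    which(ok)
  })
  if (any(lengths(feas) == 0L))
    return(new("AssignmentSet",
               solutions = matrix(integer(0), 0L, k,
                                  dimnames = list(NULL, problem@classLabels)),
               status = "ok", problem = problem))

  order_ <- order(lengths(feas), seq_len(k))  # fail-first heuristic
  sols <- list()
  overflow <- FALSE
  assign_ <- integer(k)
  rem <- caps
  recurse <- function(step) {
    if (overflow) return()
    if (step > k) {
      if (all(rem == 0L)) {
        if (length(sols) >= cap) { overflow <<- TRUE; return() }
        sols[[length(sols) + 1L]] <<- assign_
      }
      return()
    }
    cl <- order_[step]
    for (j in feas[[cl]]) {
      if (rem[j] >= sizes[cl]) {
        rem[j] <<- rem[j] - sizes[cl]
        assign_[cl] <<- j
        recurse(step + 1L)
        rem[j] <<- rem[j] + sizes[cl]
        if (overflow) return()
      }
    }
  }
  recurse(1L)
  m <- if (length(sols)) do.call(rbind, sols) else matrix(integer(0), 0L, k)
  colnames(m) <- problem@classLabels
  if (nrow(m) > 1L) m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  new("AssignmentSet", solutions = m,
      status = if (overflow) "overflow" else "ok", problem = problem)
}

#' Extract consensus dyads from a solution set
#'
#' A consensus dyad is a (class, peak) pair present in every enumerated
#' solution; being invariant over the whole solution space, it is deemed
#' correct and is the unit the learner commits to the database. A set
#' with `overflow` status is a contract error: when the solution space was
#' not fully explored, nothing can be deemed invariant.
#'
#' @param x an [AssignmentSet-class] with status `"ok"`.
#' @return data.frame with columns `class` (class index), `peak` (peak
#'   index) and `delta` (the peak position in ppm); zero rows when there
#'   are no solutions or no invariant pairs.
#' @export
consensusDyads <- function(x) {
  stopifnot(is(x, "AssignmentSet"))
  if (x@status == "overflow")
    stop("consensus is undefined for an overflowed enumeration", call. = FALSE)
  m <- x@solutions
  empty <- data.frame(class = integer(0), peak = integer(0),
                      delta = numeric(0))
  if (nrow(m) == 0L) return(empty)
  fixed <- which(apply(m, 2L, function(col) length(unique(col)) == 1L))
  if (length(fixed) == 0L) return(empty)
  peak <- m[1L, fixed]
  data.frame(class = as.integer(fixed), peak = as.integer(peak),
             delta = x@problem@peaks$position[peak])
}

#' The five-proton worked assignment example
#'
#' A compact worked example: five singleton proton classes a-e and five
#' unit-integral peaks at 1.30, 2.52, 4.16, 7.47 and 8.27 ppm, with the
#' feasibility structure that classes a and b are interchangeable over the
#' two upfield peaks, d and e over the two downfield peaks, and c is
#' pinned to 4.16 ppm (expressed as per-class shift windows). Enumeration
#' yields exactly 4 solutions; only the (c, 4.16 ppm) pair is present in
#' all of them, so it is the single consensus dyad the learner would
#' commit.
#'
#' @return an [AssignmentProblem-class].
#' @examples
#' sols <- enumerateAssignments(fiveProtonExample())
#' nrow(solutionMatrix(sols))   # 4
#' consensusDyads(sols)$delta   # 4.16
#' @export
fiveProtonExample <- function() {
  assignmentProblem(
    classSizes = rep(1L, 5L),
    positions = c(1.30, 2.52, 4.16, 7.47, 8.27),
    integrals = rep(1L, 5L),
    centers = c(1.91, 1.91, 4.16, 7.87, 7.87),
    tolerances = c(0.65, 0.65, 0.01, 0.45, 0.45),
    labels = letters[1:5],
    id = "five-proton-example")
}
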