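#' @import methods
NULL

#' Molecule: a labelled molecular graph with (optionally) explicit hydrogens
#'
#' A `Molecule` holds the atom and bond tables of one connected compound.
#' Atoms carry an element symbol and a formal charge; bonds carry the two
#' endpoint indices and an order code (1, 2, 3, or 4 for aromatic, as in
#' MDL molfiles). Hydrogens may be absent after reading a file; call
#' [completeHydrogens()] before any per-proton operation.
#'
#' @slot atoms data.frame with columns `symbol` (character) and `charge`
#'   (integer formal charge).
#' @slot bonds data.frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (integer; 4 = aromatic).
#' @slot id character(1), record identifier.
#'
#' @seealso [readSDF()], [completeHydrogens()], [protonClasses()]
#' @export
setClass("Molecule",
  representation(atoms = "data.frame", bonds = "data.frame", id = "character"))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  if (!all(c("symbol", "charge") %in% names(a)))
    msgs <- c(msgs, "atoms must have columns 'symbol' and 'charge'")
  if (!all(c("from", "to", "order") %in% names(b)))
    msgs <- c(msgs, "bonds must have columns 'from', 'to' and 'order'")
  if (length(msgs) == 0L && nrow(b) > 0L) {
    n <- nrow(a)
    if (any(b$from < 1L | b$from > n | b$to < 1L | b$to > n))
      msgs <- c(msgs, "bond endpoint out of atom range")
    if (any(b$from == b$to))
      msgs <- c(msgs, "self-bonds are not allowed")
    if (!all(b$order %in% c(1L, 2L, 3L, 4L)))
      msgs <- c(msgs, "bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (length(object@id) != 1L) msgs <- c(msgs, "id must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Molecule from atom and bond tables
#'
#' @param symbols character vector of element symbols.
#' @param bonds data.frame (or 3-column matrix) with columns `from`, `to`,
#'   `order`; order 4 denotes an aromatic bond.
#' @param charges integer vector of formal charges (default all 0).
#' @param id record identifier.
#' @return A [Molecule-class] object.
#' @examples
#' # methane with explicit hydrogens
#' m <- molecule(c("C", "H", "H", "H", "H"),
#'               data.frame(from = 1, to = 2:5, order = 1))
#' atomCount(m)
#' @export
molecule <- function(symbols, bonds, charges = integer(length(symbols)),
                     id = "mol") {
  bonds <- as.data.frame(bonds)
  names(bonds)[1:3] <- c("from", "to", "order")
  bonds$from <- as.integer(bonds$from)
  bonds$to <- as.integer(bonds$to)
  bonds$order <- as.integer(bonds$order)
  new("Molecule",
      atoms = data.frame(symbol = as.character(symbols),
                         charge = as.integer(charges)),
      bonds = bonds, id = as.character(id))
}

#' ShiftDatabase: observed (fragment, shift) entries for prediction
#'
#' A multiset of (HOSE code, radius, shift) observations harvested from
#' assignments. Multiple entries may exist per (code, radius) key; lookup
#' is exact string match on the code. Entries are deduplicated on the full
#' tuple (code, radius, delta, molecule id) so re-learning an identical
#' dyad in a later iteration is a no-op.
#'
#' @slot entries data.frame with columns `code`, `radius`, `delta`,
#'   `moleculeId`, `iteration`.
#' @slot rMin,rMax integer radius bounds used when adding observations.
#' @slot index environment mapping "code\\tradius" keys to entry row indices
#'   (rebuilt whenever entries change; never mutate it directly).
#' @seealso [shiftDatabase()], [addObservation()], [predictShift()]
#' @export
setClass("ShiftDatabase",
  representation(entries = "data.frame", rMin = "integer", rMax = "integer",
                 index = "environment"))

setValidity("ShiftDatabase", function(object) {
  e <- object@entries
  need <- c("code", "radius", "delta", "moleculeId", "iteration")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e) > 0L && any(!is.finite(e$delta)))
    return("all deltas must be finite")
  if (object@rMin < 1L || object@rMin > object@rMax)
    return("need 1 <= rMin <= rMax")
  TRUE
})

#' ShiftPrediction: the result of one predictor query
#'
#' @slot delta numeric(1), predicted shift in ppm (median over matches);
#'   `NA` when status is "failed".
#' @slot epsilon numeric(1), uncertainty in ppm (sample standard deviation
#'   of the matches); `NA` when fewer than two matches.
#' @slot m integer(1), number of matching database entries.
#' @slot radiusUsed integer(1), the sphere radius at which the match was
#'   found; `NA` when failed.
#' @slot status "ok" or "failed".
#' @export
setClass("ShiftPrediction",
  representation(delta = "numeric", epsilon = "numeric", m = "integer",
                 radiusUsed = "integer", status = "character"))

setValidity("ShiftPrediction", function(object) {
  if (!object@status %in% c("ok", "failed")) return("status must be ok/failed")
  if (object@status == "ok" && object@m < 1L) return("ok prediction needs m >= 1")
  if (object@status == "ok" && object@m >= 2L && is.na(object@epsilon))
    return("epsilon must be defined when m >= 2")
  TRUE
})

#' AssignmentProblem: classes, peaks and per-class shift windows
#'
#' Holds everything the enumerator needs: proton equivalence class sizes,
#' the peak list with integer integrals, and an optional shift window
#' (centre, tolerance) per class derived from predictions.
#'
#' @slot classSizes integer vector, one entry per proton class.
#' @slot classLabels character labels (parallel to `classSizes`).
#' @slot peaks data.frame with columns `position`, `integral`,
#'   `integerIntegral`.
#' @slot centers,tolerances numeric vectors (one per class); `NA` centre
#'   means the class is unconstrained.
#' @slot moleculeId character(1).
#' @seealso [buildProblem()], [enumerateAssignments()]
#' @export
setClass("AssignmentProblem",
  representation(classSizes = "integer", classLabels = "character",
                 peaks = "data.frame", centers = "numeric",
                 tolerances = "numeric", moleculeId = "character"))

setValidity("AssignmentProblem", function(object) {
  k <- length(object@classSizes)
  if (any(object@classSizes < 1L)) return("class sizes must be >= 1")
  if (length(object@classLabels) != k) return("one label per class required")
  if (length(object@centers) != k || length(object@tolerances) != k)
    return("centers and tolerances must be parallel to classes")
  if (!all(c("position", "integral", "integerIntegral") %in%
           names(object@peaks)))
    return("peaks need columns position, integral, integerIntegral")
  TRUE
})

#' AssignmentSet: all solutions of an assignment problem
#'
#' @slot solutions integer matrix, one row per solution, one column per
#'   class (in problem class order), entries are peak indices.
#' @slot status "ok" if the enumeration completed, "overflow" if it was
#'   aborted at the solution cap (nothing may be learnt then).
#' @slot problem the [AssignmentProblem-class] that was solved.
#' @seealso [enumerateAssignments()], [consensusDyads()]
#' @export
setClass("AssignmentSet",
  representation(solutions = "matrix", status = "character",
                 problem = "AssignmentProblem"))

setValidity("AssignmentSet", function(object) {
  if (!object@status %in% c("ok", "overflow"))
    return("status must be ok or overflow")
  TRUE
})

## ------------------------------------------------------------------
## Generics and accessors
## ------------------------------------------------------------------

#' Number of atoms in a molecule
#' @param x a [Molecule-class]
#' @return integer(1)
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname atomCount
#' @export
setMethod("atomCount", "Molecule", function(x) nrow(x@atoms))

#' Record identifier of a molecule
#' @param x a [Molecule-class]
#' @return character(1)
#' @export
setGeneric("molId", function(x) standardGeneric("molId"))

#' @rdname molId
#' @export
setMethod("molId", "Molecule", function(x) x@id)

#' Atom table of a molecule
#' @param x a [Molecule-class]
#' @return data.frame with columns `symbol`, `charge`
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "Molecule", function(x) x@atoms)

#' Bond table of a molecule
#' @param x a [Molecule-class]
#' @return data.frame with columns `from`, `to`, `order`
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' @rdname bondTable
#' @export
setMethod("bondTable", "Molecule", function(x) x@bonds)

#' Number of entries in a shift database
#' @param x a [ShiftDatabase-class]
#' @return integer(1)
#' @export
setGeneric("nEntries", function(x) standardGeneric("nEntries"))

#' @rdname nEntries
#' @export
setMethod("nEntries", "ShiftDatabase", function(x) nrow(x@entries))

#' Entry table of a shift database
#' @param x a [ShiftDatabase-class]
#' @return data.frame with columns `code`, `radius`, `delta`, `moleculeId`,
#'   `iteration`
#' @export
setGeneric("shiftEntries", function(x) standardGeneric("shiftEntries"))

#' @rdname shiftEntries
#' @export
setMethod("shiftEntries", "ShiftDatabase", function(x) x@entries)

#' Solution matrix of an assignment set
#' @param x an [AssignmentSet-class]
#' @return integer matrix (solutions x classes) of peak indices
#' @export
setGeneric("solutionMatrix", function(x) standardGeneric("solutionMatrix"))

#' @rdname solutionMatrix
#' @export
setMethod("solutionMatrix", "AssignmentSet", function(x) x@solutions)

#' Enumeration status of an assignment set
#' @param x an [AssignmentSet-class]
#' @return "ok" or "overflow"
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))

#' @rdname solutionStatus
#' @export
setMethod("solutionStatus", "AssignmentSet", function(x) x@status)

#' Prediction status
#' @param x a [ShiftPrediction-class]
#' @return "ok" or "failed"
#' @export
setGeneric("predictionStatus", function(x) standardGeneric("predictionStatus"))

#' @rdname predictionStatus
#' @export
setMethod("predictionStatus", "ShiftPrediction", function(x) x@status)

#' Predicted shift, uncertainty, match count and radius of a prediction
#' @param x a [ShiftPrediction-class]
#' @return numeric/integer scalar
#' @export
setGeneric("predictedShift", function(x) standardGeneric("predictedShift"))

#' @rdname predictedShift
#' @export
setMethod("predictedShift", "ShiftPrediction", function(x) x@delta)

#' @rdname predictedShift
#' @export
setGeneric("uncertainty", function(x) standardGeneric("uncertainty"))

#' @rdname predictedShift
#' @export
setMethod("uncertainty", "ShiftPrediction", function(x) x@epsilon)

#' @rdname predictedShift
#' @export
setGeneric("matchCount", function(x) standardGeneric("matchCount"))

#' @rdname predictedShift
#' @export
setMethod("matchCount", "ShiftPrediction", function(x) x@m)

#' @rdname predictedShift
#' @export
setGeneric("radiusUsed", function(x) standardGeneric("radiusUsed"))

#' @rdname predictedShift
#' @export
setMethod("radiusUsed", "ShiftPrediction", function(x) x@radiusUsed)

## show methods ------------------------------------------------------

setMethod("show", "Molecule", function(object) {
  nh <- sum(object@atoms$symbol == "H")
  cat(sprintf("Molecule '%s': %d atoms (%d H), %d bonds\n",
              object@id, nrow(object@atoms), nh, nrow(object@bonds)))
})

setMethod("show", "ShiftDatabase", function(object) {
  cat(sprintf("ShiftDatabase: %d entries, %d distinct (code, radius) keys, radii %d..%d\n",
              nrow(object@entries),
              length(ls(object@index, all.names = TRUE)),
              object@rMin, object@rMax))
})

setMethod("show", "ShiftPrediction", function(object) {
  if (object@status == "failed") {
    cat("ShiftPrediction: failed (no match at any allowed radius)\n")
  } else {
    cat(sprintf("ShiftPrediction: %.3f ppm (epsilon %s, m = %d, radius %d)\n",
                object@delta,
                if (is.na(object@epsilon)) "NA" else sprintf("%.3f", object@epsilon),
                object@m, object@radiusUsed))
  }
})

setMethod("show", "AssignmentProblem", function(object) {
  cat(sprintf("AssignmentProblem '%s': %d classes (sizes %s), %d peaks, %d shift-constrained\n",
              object@moleculeId, length(object@classSizes),
              paste(object@classSizes, collapse = ","),
              nrow(object@peaks), sum(!is.na(object@centers))))
})

setMethod("show", "AssignmentSet", function(object) {
  cat(sprintf("AssignmentSet: %d solutions (%s)\n",
              nrow(object@solutions), object@status))
})
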