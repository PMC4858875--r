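#' Create an empty shift database
#'
#' @param rMin,rMax sphere radius range used when adding observations
#'   (defaults 2 and 4).
#' @return an empty [ShiftDatabase-class].
#' @export
shiftDatabase <- function(rMin = 2L, rMax = 4L) {
  rMin <- as.integer(rMin); rMax <- as.integer(rMax)
  entries <- data.frame(code = character(0), radius = integer(0),
                        delta = numeric(0), moleculeId = character(0),
                        iteration = integer(0), stringsAsFactors = FALSE)
  new("ShiftDatabase", entries = entries, rMin = rMin, rMax = rMax,
      index = buildIndex(entries))
}

buildIndex <- function(entries) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(entries)) {
    keys <- paste(entries$code, entries$radius, sep = "\t")
    byKey <- split(seq_len(nrow(entries)), keys)
    for (k in names(byKey)) assign(k, byKey[[k]], envir = idx)
  }
  idx
}

#' Add observations to a shift database
#'
#' `addObservation` records one assigned proton: one entry per radius
#' `rMin..rMax` of the database, keyed by the proton's HOSE code at that
#' radius. `addEntries` commits a pre-built entry table (the learner's
#' batch path). Both deduplicate on (code, radius, delta, moleculeId), so
#' re-learning an identical dyad later is a no-op, and equivalent protons
#' of one molecule assigned to the same peak collapse to one entry per
#' radius.
#'
#' @param db a [ShiftDatabase-class].
#' @param mol a hydrogen-complete [Molecule-class].
#' @param proton atom index of the assigned hydrogen.
#' @param delta observed chemical shift (ppm), finite.
#' @param iteration learning iteration the entry was produced in.
#' @param id source molecule identifier (defaults to `molId(mol)`).
#' @return the updated [ShiftDatabase-class].
#' @export
setGeneric("addObservation",
  function(db, mol, proton, delta, iteration = 0L, id = molId(mol))
    standardGeneric("addObservation"))

#' @rdname addObservation
#' @export
setMethod("addObservation", "ShiftDatabase",
  function(db, mol, proton, delta, iteration = 0L, id = molId(mol)) {
    stopifnot(is.finite(delta))
    codes <- hoseCodes(mol, proton, db@rMin, db@rMax)
    addEntries(db, data.frame(code = unname(codes),
                              radius = as.integer(names(codes)),
                              delta = delta, moleculeId = id,
                              iteration = as.integer(iteration),
                              stringsAsFactors = FALSE))
  })

#' @rdname addObservation
#' @param newEntries data.frame with columns `code`, `radius`, `delta`,
#'   `moleculeId`, `iteration`.
#' @export
addEntries <- function(db, newEntries) {
  stopifnot(is(db, "ShiftDatabase"))
  if (NROW(newEntries) == 0L) return(db)
  all <- rbind(db@entries, newEntries[names(db@entries)])
  dedupKey <- paste(all$code, all$radius, all$delta, all$moleculeId,
                    sep = "\t")
  all <- all[!duplicated(dedupKey), , drop = FALSE]
  rownames(all) <- NULL
  new("ShiftDatabase", entries = all, rMin = db@rMin, rMax = db@rMax,
      index = buildIndex(all))
}

#' Predict a proton's chemical shift by cascading HOSE lookup
#'
#' Queries the database with the proton's code at radius `rMax`; on a miss
#' the radius is decreased one step at a time until a match is found or
#' the radius would drop below `rMin`, in which case a failed prediction
#' is returned. On a hit, the predicted shift is the median of all
#' matching entries' shifts, with uncertainty equal to their sample
#' standard deviation (defined only for two or more matches). Larger
#' radii are never skipped: the first radius with at least one match
#' determines the result.
#'
#' @param db a [ShiftDatabase-class].
#' @param mol a hydrogen-complete [Molecule-class] (ignored when `codes`
#'   is supplied).
#' @param proton atom index of the queried hydrogen.
#' @param codes optional pre-computed named code vector as returned by
#'   [hoseCodes()] (names = radii); supply this in inner loops to avoid
#'   re-encoding.
#' @return a [ShiftPrediction-class].
#' @examples
#' db <- shiftDatabase()
#' meth <- completeHydrogens(molecule("C",
#'   data.frame(from = integer(0), to = integer(0), order = integer(0)),
#'   id = "methane"))
#' predictionStatus(predictShift(db, meth, 2))  # "failed": empty database
#' @export
setGeneric("predictShift",
  function(db, mol = NULL, proton = NULL, codes = NULL)
    standardGeneric("predictShift"))

#' @rdname predictShift
#' @export
setMethod("predictShift", "ShiftDatabase",
  function(db, mol = NULL, proton = NULL, codes = NULL) {
    if (is.null(codes)) {
      stopifnot(is(mol, "Molecule"), !is.null(proton))
      codes <- hoseCodes(mol, proton, db@rMin, db@rMax)
    }
    radii <- as.integer(names(codes))
    for (r in sort(radii, decreasing = TRUE)) {
      key <- paste(codes[[as.character(r)]], r, sep = "\t")
      rows <- db@index[[key]]
      if (!is.null(rows) && length(rows)) {
        deltas <- db@entries$delta[rows]
        m <- length(deltas)
        return(new("ShiftPrediction",
                   delta = stats::median(deltas),
                   epsilon = if (m >= 2L) stats::sd(deltas) else NA_real_,
                   m = m, radiusUsed = r, status = "ok"))
      }
    }
    new("ShiftPrediction", delta = NA_real_, epsilon = NA_real_,
        m = 0L, radiusUsed = NA_integer_, status = "failed")
  })

#' Iteration-scaled prediction uncertainty
#'
#' The raw uncertainty (the sample standard deviation of the matching
#' shifts) is a poor estimator for small samples and early iterations, so
#' it is inflated by the factor `1 + m^(-I/2)`, where `m` is the match
#' count and `I` the current learning iteration. The factor starts at 2
#' (iteration 0) and decays towards 1 as iterations accumulate, faster
#' for larger samples.
#'
#' @param epsilon raw uncertainty (ppm), from a prediction with `m >= 2`.
#' @param m match count, >= 2 (single-match predictions carry no usable
#'   uncertainty; callers must use the fallback tolerance instead).
#' @param I iteration index, >= 0.
#' @return scaled uncertainty in ppm.
#' @examples
#' scaledUncertainty(0.1, m = 4, I = 2)  # 0.1 * (1 + 1/4) = 0.125
#' @export
scaledUncertainty <- function(epsilon, m, I) {
  if (any(m < 2L)) stop("scaledUncertainty requires m >= 2", call. = FALSE)
  stopifnot(I >= 0, epsilon >= 0)
  epsilon * (1 + m^(-I / 2))
}

#' Allowed shift error for assignment matching
#'
#' A class may be assigned to a peak only if the peak position lies within
#' this tolerance of the predicted shift. For predictions based on fewer
#' matches than `lowMatchThreshold` (default 2) no reasonable uncertainty
#' estimate exists and the tolerance is the 20 ppm maximum; otherwise it
#' is 3 times the iteration-scaled uncertainty, floored at
#' `toleranceFloor` so duplicate observations (epsilon 0) cannot lock out
#' every assignment.
#'
#' @param pred a successful [ShiftPrediction-class].
#' @param I iteration index.
#' @param config a [learnerConfig()] list (supplies `lowMatchThreshold`,
#'   `toleranceFloor`, `maxTolerance`).
#' @return tolerance in ppm.
#' @examples
#' p <- new("ShiftPrediction", delta = 7.2, epsilon = 0.1, m = 4L,
#'          radiusUsed = 4L, status = "ok")
#' assignmentTolerance(p, I = 2)  # 3 * 0.125 = 0.375
#' @export
assignmentTolerance <- function(pred, I, config = learnerConfig()) {
  stopifnot(is(pred, "ShiftPrediction"))
  if (pred@status != "ok")
    stop("assignmentTolerance requires a successful prediction", call. = FALSE)
  if (pred@m < config$lowMatchThreshold || pred@m < 2L || is.na(pred@epsilon))
    return(config$maxTolerance)
  max(config$toleranceFloor, 3 * scaledUncertainty(pred@epsilon, pred@m, I))
}

#' Export or import the database as a TSV table
#'
#' The on-disk interchange format is a flat tab-separated table with
#' columns `code`, `radius`, `delta_ppm`, `molecule_id`, `iteration`:
#' trivially inspectable and diffable.
#'
#' @param db a [ShiftDatabase-class].
#' @param path file path.
#' @return `exportShiftTable`: `path` invisibly; `importShiftTable`: a
#'   [ShiftDatabase-class].
#' @export
exportShiftTable <- function(db, path) {
  e <- db@entries
  utils::write.table(
    data.frame(code = e$code, radius = e$radius, delta_ppm = e$delta,
               molecule_id = e$moleculeId, iteration = e$iteration),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exportShiftTable
#' @param rMin,rMax radius range of the reconstructed database.
#' @export
importShiftTable <- function(path, rMin = 2L, rMax = 4L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(code = "character"))
  db <- shiftDatabase(rMin, rMax)
  addEntries(db, data.frame(code = tab$code, radius = as.integer(tab$radius),
                            delta = tab$delta_ppm,
                            moleculeId = as.character(tab$molecule_id),
                            iteration = as.integer(tab$iteration),
                            stringsAsFactors = FALSE))
}
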