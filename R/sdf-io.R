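#' Read molecules from an SDF / MDL molfile (V2000)
#'
#' Parses the counts line, atom block, bond block and `M  CHG` formal-charge
#' property lines of each record. Hydrogen counts are taken as-is from the
#' file; call [completeHydrogens()] afterwards. Disconnected records (e.g.
#' salts) are reduced to their largest connected component with a warning,
#' since the spectra in scope are single-compound. V3000 records are
#' rejected.
#'
#' @param path path to an `.sdf` or `.mol` file.
#' @return list of [Molecule-class] objects, in file order. Record ids are
#'   taken from the molfile title line when non-empty, else `"record<i>"`.
#' @examples
#' sdf <- tempfile(fileext = ".sdf")
#' writeSDF(list(molecule("C", data.frame(from = integer(0),
#'   to = integer(0), order = integer(0)), id = "c1")), sdf)
#' length(readSDF(sdf))
#' @export
readSDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  # split into records on $$$$ delimiters; a final record may lack one
  delims <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, delims + 1L)
  ends <- c(delims - 1L, length(lines))
  mols <- list()
  rec <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > ends[i]) next
    block <- lines[starts[i]:ends[i]]
    if (!any(nzchar(trimws(block)))) next
    rec <- rec + 1L
    mols[[rec]] <- parseMolBlock(block, rec)
  }
  mols
}

parseMolBlock <- function(block, recordIndex) {
  oops <- function(...) stop(sprintf("record %d: %s", recordIndex,
                                     sprintf(...)), call. = FALSE)
  if (length(block) < 4L) oops("truncated record (no counts line)")
  title <- trimws(block[1L])
  counts <- block[4L]
  if (grepl("V3000", counts)) oops("V3000 molfiles are not supported")
  nAtoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nBonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(nAtoms) || is.na(nBonds) || nAtoms < 1L || nBonds < 0L)
    oops("malformed counts line: '%s'", counts)
  if (length(block) < 4L + nAtoms + nBonds)
    oops("record shorter than counts line promises")
  atomLines <- block[4L + seq_len(nAtoms)]
  bondLines <- if (nBonds > 0L) block[4L + nAtoms + seq_len(nBonds)] else character(0)

  symbol <- trimws(substr(atomLines, 32L, 34L))
  if (any(!nzchar(symbol))) oops("atom line without element symbol")
  # old-style charge column (0,1..7 codes); superseded by M  CHG if present
  oldChg <- suppressWarnings(as.integer(substr(atomLines, 37L, 39L)))
  oldChg[is.na(oldChg)] <- 0L
  chargeMap <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- unname(chargeMap[as.character(oldChg)])
  charge[is.na(charge)] <- 0L

  from <- suppressWarnings(as.integer(substr(bondLines, 1L, 3L)))
  to <- suppressWarnings(as.integer(substr(bondLines, 4L, 6L)))
  order <- suppressWarnings(as.integer(substr(bondLines, 7L, 9L)))
  if (nBonds > 0L) {
    if (any(is.na(from) | is.na(to) | is.na(order)))
      oops("malformed bond block")
    if (any(from < 1L | from > nAtoms | to < 1L | to > nAtoms))
      oops("bond references atom outside 1..%d", nAtoms)
    if (any(from == to)) oops("self-bond in bond block")
    if (any(!order %in% 1:4)) oops("unsupported bond type (only 1,2,3,4)")
  }

  # M  CHG property lines override the atom-block charge column entirely
  chgLines <- grep("^M  CHG", block, value = TRUE)
  if (length(chgLines)) {
    charge <- integer(nAtoms)
    for (ln in chgLines) {
      toks <- scan(text = sub("^M  CHG", "", ln), what = integer(),
                   quiet = TRUE)
      k <- toks[1L]
      pairs <- matrix(toks[-1L], ncol = 2L, byrow = TRUE)
      if (nrow(pairs) != k) oops("malformed M  CHG line")
      if (any(pairs[, 1L] < 1L | pairs[, 1L] > nAtoms))
        oops("M  CHG references atom outside 1..%d", nAtoms)
      charge[pairs[, 1L]] <- pairs[, 2L]
    }
  }

  mol <- molecule(symbol,
                  data.frame(from = from, to = to, order = order),
                  charges = charge,
                  id = if (nzchar(title)) title else paste0("record", recordIndex))
  comps <- connectedComponents(mol)
  if (length(comps) > 1L) {
    warning(sprintf("record %d ('%s'): %d disconnected components, keeping largest",
                    recordIndex, mol@id, length(comps)))
    sizes <- lengths(comps)
    mol <- inducedMolecule(mol, comps[[which.max(sizes)]])
  }
  mol
}

#' Write molecules as a V2000 SDF file
#'
#' Round-trip companion of [readSDF()]; used by the synthetic corpus writer.
#' Coordinates are written as zeros (no 3D information is modelled).
#'
#' @param mols list of [Molecule-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSDF <- function(mols, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol@atoms; b <- mol@bonds
    writeLines(c(mol@id, "  hoseNMR", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, a$symbol), con)
    if (nrow(b))
      writeLines(sprintf("%3d%3d%3d  0", b$from, b$to, b$order), con)
    chg <- which(a$charge != 0L)
    for (i in chg)
      writeLines(sprintf("M  CHG  1 %3d %3d", i, a$charge[i]), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read and write peak lists
#'
#' Peak lists are tab- or comma-separated tables with a header naming at
#' least `delta_ppm` and `integral`.
#'
#' @param path file path.
#' @return `readPeakList`: data.frame with columns `position` (ppm) and
#'   `integral`.
#' @export
readPeakList <- function(path) {
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("delta_ppm", "integral") %in% names(tab)))
    stop("peak list needs columns 'delta_ppm' and 'integral': ", path)
  data.frame(position = as.numeric(tab$delta_ppm),
             integral = as.numeric(tab$integral))
}

#' @rdname readPeakList
#' @param peaks data.frame with columns `position` and `integral`.
#' @export
writePeakList <- function(peaks, path) {
  utils::write.table(
    data.frame(delta_ppm = peaks$position, integral = peaks$integral),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write reference assignment tables
#'
#' Reference dyads for evaluation: one row per assigned proton, columns
#' `molecule_id`, `atom_index` (index of a hydrogen atom in the
#' hydrogen-complete molecule) and `delta_ppm`.
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
readReferenceShifts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("molecule_id", "atom_index", "delta_ppm")
  if (!all(need %in% names(tab)))
    stop("reference table needs columns ", paste(need, collapse = ", "))
  tab[need]
}

#' @rdname readReferenceShifts
#' @param refs data.frame with columns `molecule_id`, `atom_index`,
#'   `delta_ppm`.
#' @export
writeReferenceShifts <- function(refs, path) {
  utils::write.table(refs[c("molecule_id", "atom_index", "delta_ppm")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
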