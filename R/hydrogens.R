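#' Complete implicit hydrogens on a molecule
#'
#' Adds hydrogen atoms (single bonds) until every heavy atom reaches its
#' default valence, respecting formal charge: C 4 − |q|, N 3 + q, O 2 + q,
#' halogens 1 + q, S the smallest of 2/4/6 at or above the current
#' bond-order sum, P the smaller of 3/5. Aromatic bonds count 1.5 towards
#' the bond-order sum (two aromatic bonds = 3, as for a benzene carbon).
#' Existing explicit hydrogens are preserved; the call is idempotent.
#'
#' @param mol a [Molecule-class].
#' @return a hydrogen-complete [Molecule-class]; added hydrogens are
#'   appended after the existing atoms.
#' @examples
#' eth <- molecule(c("C", "C", "O"),
#'                 data.frame(from = c(1, 2), to = c(2, 3), order = 1),
#'                 id = "ethanol")
#' atomCount(completeHydrogens(eth))  # 3 heavy + 6 H
#' @export
completeHydrogens <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  sums <- bondOrderSums(mol)
  a <- mol@atoms
  newH <- integer(0)  # heavy atom index for each hydrogen to add
  for (i in seq_len(nrow(a))) {
    sym <- a$symbol[i]; q <- a$charge[i]
    used <- as.integer(round(sums[i]))
    target <- switch(sym,
      C = 4L - abs(q),
      N = 3L + q,
      O = 2L + q,
      S = {v <- c(2L, 4L, 6L); v <- v[v >= used]
           if (length(v)) v[1L] else -1L},
      P = {v <- c(3L, 5L); v <- v[v >= used]
           if (length(v)) v[1L] else -1L},
      F = , Cl = , Br = , I = 1L + q,
      H = 1L,
      used)  # unknown elements: leave as drawn, add nothing
    if (used > target)
      stop(sprintf("valence error: atom %d (%s, charge %+d) has bond-order sum %d > allowed %d",
                   i, sym, q, used, target), call. = FALSE)
    nAdd <- target - used
    if (sym != "H" && nAdd > 0L) newH <- c(newH, rep(i, nAdd))
  }
  if (length(newH) == 0L) return(mol)
  nOld <- nrow(a)
  atoms <- rbind(a, data.frame(symbol = rep("H", length(newH)),
                               charge = rep(0L, length(newH))))
  bonds <- rbind(mol@bonds,
                 data.frame(from = newH,
                            to = nOld + seq_along(newH),
                            order = rep(1L, length(newH))))
  new("Molecule", atoms = atoms, bonds = bonds, id = mol@id)
}

#' Proton equivalence classes of a molecule
#'
#' Partitions the hydrogen atoms by constitutional (graph-automorphism)
#' equivalence: two protons are equivalent when some automorphism of the
#' labelled molecular graph maps one onto the other. Equivalent protons
#' contribute to the same NMR signal, so assignment operates on these
#' classes, never on individual protons. Equivalence is computed by
#' iterative neighbourhood-label (Morgan-style) refinement over
#' (element, charge) seed labels and bond orders; stereochemistry and
#' diastereotopicity are outside the model.
#'
#' @param mol a hydrogen-complete [Molecule-class].
#' @return list of integer vectors, each the sorted atom indices of one
#'   class, ordered by smallest member index. The vectors' lengths are the
#'   class sizes (the expected peak integrals).
#' @examples
#' benzene <- completeHydrogens(molecule(rep("C", 6),
#'   data.frame(from = 1:6, to = c(2:6, 1), order = 4), id = "benzene"))
#' lengths(protonClasses(benzene))  # 6
#' @export
protonClasses <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  colors <- atomColors(mol)
  h <- which(isHydrogen(mol))
  if (length(h) == 0L) return(list())
  groups <- split(h, colors[h])
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, min, integer(1)))]
}

# Morgan-style iterative refinement; returns canonical integer colors.
# Signatures are built from sorted neighbour (bond, color) strings, so the
# result is invariant under atom input order.
atomColors <- function(mol) {
  adj <- adjacencyList(mol)
  n <- atomCount(mol)
  sig <- paste(mol@atoms$symbol, mol@atoms$charge)
  colors <- match(sig, sort(unique(sig)))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      nbSig <- if (nrow(nb)) sort(paste(nb[, 2L], colors[nb[, 1L]])) else character(0)
      paste(colors[i], paste(nbSig, collapse = "|"))
    }, character(1))
    newColors <- match(sig, sort(unique(sig)))
    if (length(unique(newColors)) == length(unique(colors))) {
      return(newColors)
    }
    colors <- newColors
  }
}
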