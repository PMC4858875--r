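#' Extract the n-sphere (spherical environment) around a proton
#'
#' The n-sphere of radius `r` around a proton is the substructure spanned
#' by all atoms up to `r` bonds from it; shell `d` holds the atoms at graph
#' distance exactly `d`. Distances are counted from the proton itself, so
#' shell 1 is the attached heavy atom. Hydrogens other than the centre
#' proton are summarised as attached-H counts on their heavy atom rather
#' than listed as shell members, keeping the radius semantics on the
#' heavy-atom skeleton.
#'
#' @param mol a hydrogen-complete [Molecule-class].
#' @param proton atom index of a hydrogen atom.
#' @param r sphere radius, >= 1.
#' @return list with elements `center` (the proton index), `radius`, and
#'   `shells`: a list of data.frames (one per distance 1..r, possibly
#'   empty) with columns `atom`, `symbol`, `charge`, `nH`.
#' @export
nSphere <- function(mol, proton, r) {
  stopifnot(is(mol, "Molecule"), r >= 1L)
  if (mol@atoms$symbol[proton] != "H")
    stop("atom ", proton, " is not a hydrogen", call. = FALSE)
  adj <- adjacencyList(mol)
  dist <- bfsDistances(adj, proton)
  hFlag <- isHydrogen(mol)
  nH <- vapply(seq_len(atomCount(mol)),
               function(i) sum(hFlag[adj[[i]][, 1L]]), numeric(1))
  shells <- lapply(seq_len(r), function(d) {
    atoms <- which(!is.na(dist) & dist == d & !hFlag)
    data.frame(atom = atoms,
               symbol = mol@atoms$symbol[atoms],
               charge = mol@atoms$charge[atoms],
               nH = as.integer(nH[atoms]))
  })
  list(center = proton, radius = as.integer(r), shells = shells)
}

#' Encode a proton environment as a canonical HOSE-style code
#'
#' Serialises the n-sphere around a proton as a deterministic string: a
#' recursive, breadth-consistent expansion of the attached heavy atom in
#' which every branch lists its deeper neighbours in sorted order. Two
#' protons receive byte-identical codes exactly when their environments up
#' to radius `r` are indistinguishable, regardless of atom input order.
#' The dialect is this package's own (the learning loop is closed over the
#' encoder, so only internal consistency matters); it is not
#' bit-compatible with CSEARCH/NMRPredict HOSE strings.
#'
#' Grammar: an atom is written `symbol[Hk][+q|-q]` (attached-hydrogen count
#' and formal charge when non-zero), followed, when it has in-sphere
#' continuations, by a parenthesised, comma-separated, lexicographically
#' sorted list of branches. A branch is a bond symbol (`-` single, `=`
#' double, `#` triple, `:` aromatic) followed by the code of the
#' next-shell atom, or by the ring-closure marker `&` when the bond runs
#' to an atom in the same shell. Atoms reachable along several shortest
#' paths are expanded under each of their predecessors.
#'
#' @inheritParams nSphere
#' @return character(1), the code.
#' @examples
#' benzene <- completeHydrogens(molecule(rep("C", 6),
#'   data.frame(from = 1:6, to = c(2:6, 1), order = 4), id = "benzene"))
#' h <- which(atomTable(benzene)$symbol == "H")
#' hoseCode(benzene, h[1], 2)
#' @export
hoseCode <- function(mol, proton, r) {
  stopifnot(is(mol, "Molecule"), r >= 1L)
  if (mol@atoms$symbol[proton] != "H")
    stop("atom ", proton, " is not a hydrogen", call. = FALSE)
  adj <- adjacencyList(mol)
  encodeFromAdjacency(mol, adj, proton, r)
}

# Shared worker so callers that loop over protons/radii can reuse the
# adjacency list.
encodeFromAdjacency <- function(mol, adj, proton, r) {
  dist <- bfsDistances(adj, proton)
  hFlag <- isHydrogen(mol)
  syms <- mol@atoms$symbol
  chg <- mol@atoms$charge
  nH <- vapply(seq_along(adj),
               function(i) sum(hFlag[adj[[i]][, 1L]]), numeric(1))
  bondSym <- c("-", "=", "#", ":")
  desc <- function(i) {
    paste0(syms[i],
           if (nH[i] > 0) paste0("H", nH[i]),
           if (chg[i] != 0L) sprintf("%+d", chg[i]))
  }
  expand <- function(i, d) {
    nb <- adj[[i]]
    branches <- character(0)
    for (k in seq_len(nrow(nb))) {
      j <- nb[k, 1L]
      if (hFlag[j] || is.na(dist[j])) next
      if (dist[j] == d + 1L && d + 1L <= r) {
        branches <- c(branches, paste0(bondSym[nb[k, 2L]], expand(j, d + 1L)))
      } else if (dist[j] == d) {
        branches <- c(branches, paste0(bondSym[nb[k, 2L]], "&"))
      }
    }
    paste0(desc(i),
           if (length(branches))
             paste0("(", paste(sort(branches), collapse = ","), ")"))
  }
  nb <- adj[[proton]]
  heavy <- nb[!hFlag[nb[, 1L]], 1L]
  if (length(heavy) != 1L)
    stop("proton ", proton, " must be bonded to exactly one heavy atom",
         call. = FALSE)
  expand(heavy, 1L)
}

#' Encode a proton at every radius in a range
#'
#' @inheritParams nSphere
#' @param rMin,rMax radius range, `1 <= rMin <= rMax`.
#' @return named character vector, one code per radius (names are the
#'   radii, ascending).
#' @export
hoseCodes <- function(mol, proton, rMin = 2L, rMax = 4L) {
  if (rMin > rMax) stop("rMin must not exceed rMax", call. = FALSE)
  stopifnot(rMin >= 1L)
  adj <- adjacencyList(mol)
  radii <- seq.int(rMin, rMax)
  codes <- vapply(radii, function(r) encodeFromAdjacency(mol, adj, proton, r),
                  character(1))
  names(codes) <- radii
  codes
}
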