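# Fixture molecules (built in code) and independent oracles.

mkMol <- function(symbols, from, to, order, id = "m", charges = NULL) {
  molecule(symbols, data.frame(from = from, to = to, order = order),
           charges = if (is.null(charges)) integer(length(symbols)) else charges,
           id = id)
}

fixMethane <- function() completeHydrogens(mkMol("C", integer(0), integer(0),
                                                 integer(0), id = "methane"))

fixEthanol <- function() completeHydrogens(
  mkMol(c("C", "C", "O"), c(1, 2), c(2, 3), c(1, 1), id = "ethanol"))

fixPropane <- function() completeHydrogens(
  mkMol(c("C", "C", "C"), c(1, 2), c(2, 3), c(1, 1), id = "propane"))

fixBenzene <- function() completeHydrogens(
  mkMol(rep("C", 6), 1:6, c(2:6, 1), rep(4, 6), id = "benzene"))

fixToluene <- function() completeHydrogens(
  mkMol(c(rep("C", 6), "C"), c(1:6, 1), c(2:6, 1, 7),
        c(rep(4, 6), 1), id = "toluene"))

fixAnisole <- function() completeHydrogens(
  mkMol(c("C", "O", rep("C", 6)), c(1, 2, 3:8), c(2, 3, c(4:8, 3)),
        c(1, 1, rep(4, 6)), id = "anisole"))

fixDimethylEther <- function() completeHydrogens(
  mkMol(c("C", "O", "C"), c(1, 2), c(2, 3), c(1, 1), id = "dme"))

fixMethylFormate <- function() completeHydrogens(
  mkMol(c("C", "O", "C", "O"), c(1, 2, 3), c(2, 3, 4), c(1, 1, 2),
        id = "methylformate"))

fixMethylAcetate <- function() completeHydrogens(
  mkMol(c("C", "O", "C", "O", "C"), c(1, 2, 3, 3), c(2, 3, 4, 5),
        c(1, 1, 2, 1), id = "methylacetate"))

# Teacher/pupil training set for batch-semantics checks: two teachers
# share the methoxy r=2 environment; the pupil (methyl acetate) is fully
# ambiguous on integrals alone and needs their learnt shift.
teacherPupilSet <- function() {
  list(
    list(molecule = fixDimethylEther(),
         peaks = data.frame(position = 3.30, integral = 6)),
    list(molecule = fixMethylFormate(),
         peaks = data.frame(position = c(3.60, 8.05), integral = c(3, 1))),
    list(molecule = fixMethylAcetate(),
         peaks = data.frame(position = c(3.67, 2.05), integral = c(3, 3))))
}

# Relabel atoms by a permutation: atom i of the result is atom perm[i] of
# the input. Returns the permuted molecule; inverse[j] gives the new index
# of old atom j.
permuteMolecule <- function(mol, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  a <- atomTable(mol)[perm, , drop = FALSE]
  b <- bondTable(mol)
  b$from <- inv[b$from]
  b$to <- inv[b$to]
  list(mol = molecule(a$symbol, b, charges = a$charge, id = molId(mol)),
       newIndex = inv)
}

# Brute-force automorphism enumeration (backtracking over an order-labelled
# adjacency matrix). Returns the proton orbit partition: the oracle for
# protonClasses() on small molecules.
oracleProtonOrbits <- function(mol) {
  n <- atomCount(mol)
  a <- atomTable(mol)
  lab <- paste(a$symbol, a$charge)
  adj <- matrix(0L, n, n)
  b <- bondTable(mol)
  for (k in seq_len(nrow(b))) {
    adj[b$from[k], b$to[k]] <- b$order[k]
    adj[b$to[k], b$from[k]] <- b$order[k]
  }
  deg <- rowSums(adj > 0)
  parent <- seq_len(n)  # union-find over atoms
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  map <- integer(n); used <- logical(n)
  recurse <- function(k) {
    if (k > n) {
      for (i in seq_len(n)) unite(i, map[i])
      return(invisible())
    }
    for (t in seq_len(n)) {
      if (used[t] || lab[t] != lab[k] || deg[t] != deg[k]) next
      ok <- TRUE
      for (u in seq_len(k - 1L)) {
        if (adj[k, u] != adj[t, map[u]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[k] <<- t; used[t] <<- TRUE
      recurse(k + 1L)
      used[t] <<- FALSE
    }
  }
  recurse(1L)
  h <- which(a$symbol == "H")
  roots <- vapply(h, findRoot, integer(1))
  groups <- split(h, roots)
  groups <- lapply(unname(groups), sort)
  groups[order(vapply(groups, min, integer(1)))]
}

samePartition <- function(p1, p2) {
  key <- function(p) sort(vapply(p, function(g) paste(sort(g), collapse = ","),
                                 character(1)))
  identical(key(p1), key(p2))
}
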