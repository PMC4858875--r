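# Internal graph helpers shared across modules.

# Adjacency list: for each atom, integer matrix with rows (neighbour, order).
adjacencyList <- function(mol) {
  n <- atomCount(mol)
  b <- mol@bonds
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- cbind(nbr = integer(0), order = integer(0))
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$from[k]]] <- rbind(adj[[b$from[k]]], c(b$to[k], b$order[k]))
      adj[[b$to[k]]] <- rbind(adj[[b$to[k]]], c(b$from[k], b$order[k]))
    }
  }
  adj
}

isHydrogen <- function(mol) mol@atoms$symbol == "H"

# Bond-order sum per atom; aromatic (4) counts 1.5.
bondOrderSums <- function(mol) {
  n <- atomCount(mol)
  s <- numeric(n)
  b <- mol@bonds
  if (nrow(b)) {
    w <- ifelse(b$order == 4L, 1.5, as.numeric(b$order))
    for (k in seq_len(nrow(b))) {
      s[b$from[k]] <- s[b$from[k]] + w[k]
      s[b$to[k]] <- s[b$to[k]] + w[k]
    }
  }
  s
}

# BFS distances from a source atom; unreachable = NA.
bfsDistances <- function(adj, source) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  queue <- source
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][, 1L]
    new <- nb[is.na(dist[nb])]
    dist[new] <- dist[v] + 1L
    queue <- c(queue, new)
  }
  dist
}

# Connected components as a list of atom index vectors.
connectedComponents <- function(mol) {
  adj <- adjacencyList(mol)
  n <- length(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    d <- bfsDistances(adj, s)
    members <- which(!is.na(d))
    seen[members] <- TRUE
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# Induced subgraph on a set of atoms (indices remapped, order preserved).
inducedMolecule <- function(mol, keep) {
  keep <- sort(keep)
  map <- integer(atomCount(mol))
  map[keep] <- seq_along(keep)
  b <- mol@bonds
  b <- b[b$from %in% keep & b$to %in% keep, , drop = FALSE]
  b$from <- map[b$from]; b$to <- map[b$to]
  new("Molecule", atoms = mol@atoms[keep, , drop = FALSE], bonds = b,
      id = mol@id)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round half away from zero (base round() is banker's rounding)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)
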