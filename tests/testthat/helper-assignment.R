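# Exhaustive assignment oracle: enumerate every class -> peak map and keep
# those with exact per-peak integral balance and all shift windows
# satisfied. Independent of the branch-and-bound path (no pruning, no
# ordering heuristic).
oracleEnumerate <- function(problem) {
  sizes <- problem@classSizes
  k <- length(sizes)
  caps <- problem@peaks$integerIntegral
  pos <- problem@peaks$position
  p <- length(caps)
  grid <- as.matrix(expand.grid(rep(list(seq_len(p)), k)))
  keep <- rep(TRUE, nrow(grid))
  for (i in seq_len(k)) {
    if (!is.na(problem@centers[i]))
      keep <- keep & abs(pos[grid[, i]] - problem@centers[i]) <=
        problem@tolerances[i]
  }
  grid <- grid[keep, , drop = FALSE]
  balanced <- vapply(seq_len(nrow(grid)), function(r) {
    load <- numeric(p)
    for (i in seq_len(k)) load[grid[r, i]] <- load[grid[r, i]] + sizes[i]
    all(load == caps)
  }, logical(1))
  m <- grid[balanced, , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- problem@classLabels
  if (nrow(m) > 1L) m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Random feasible assignment problem with <= maxClasses classes. Class
# sizes are drawn first; peaks are formed by randomly grouping classes
# (guaranteeing at least one solution), then optional shift windows are
# attached to a random subset of classes.
randomProblem <- function(maxClasses = 8L, maxPeaks = 5L,
                          constrain = TRUE) {
  k <- sample(2:maxClasses, 1L)
  sizes <- sample(1:3, k, replace = TRUE)
  p <- sample(seq_len(min(maxPeaks, k)), 1L)
  home <- sample(seq_len(p), k, replace = TRUE)
  home[sample.int(k, min(k, p))] <- seq_len(p)  # every peak gets a class
  caps <- vapply(seq_len(p), function(j) sum(sizes[home == j]), integer(1))
  pos <- sort(stats::runif(p, 0, 10))
  centers <- rep(NA_real_, k); tols <- rep(NA_real_, k)
  if (constrain) {
    for (i in which(stats::runif(k) < 0.5)) {
      centers[i] <- pos[sample.int(p, 1L)] + stats::rnorm(1, 0, 0.5)
      tols[i] <- stats::runif(1, 0.1, 3)
    }
  }
  assignmentProblem(sizes, pos, caps, centers, tols,
                    id = "random-problem")
}
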