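# Integral normalisation, branch-and-bound enumeration, consensus dyads.

test_that("integrals are rescaled to the proton count and rounded half-away", {
  eth <- fixEthanol()  # 6 protons in classes 3/2/1

  pr <- buildProblem(eth, data.frame(position = c(1.2, 3.7, 2.6),
                                     integral = c(2.9, 1.05, 2.1)))
  expect_equal(pr@peaks$integerIntegral, c(3L, 1L, 2L))

  # equal raw integrals, five singleton-classes analogue: each becomes 1
  pent <- assignmentProblem(rep(1, 5), 1:5, rep(1, 5))
  expect_equal(pent@peaks$integerIntegral, rep(1L, 5))

  # 3 protons over raw {1.6, 1.6}: scaled to {1.5, 1.5}, rounds to {2, 2}
  tcp <- completeHydrogens(mkMol(c("C", "C", "Cl", "Cl", "Cl"),
                                 c(1, 1, 1, 1), c(2, 3, 4, 5),
                                 rep(1, 4), id = "tClEthane"))
  expect_equal(sum(atomTable(tcp)$symbol == "H"), 3L)
  expect_error(
    buildProblem(tcp, data.frame(position = c(1.0, 2.0),
                                 integral = c(1.6, 1.6))),
    class = "hoseNMR_infeasible")
})

test_that("the five-proton worked example has 4 solutions and one consensus dyad", {
  ex <- fiveProtonExample()
  sols <- enumerateAssignments(ex)
  expect_equal(solutionStatus(sols), "ok")
  m <- solutionMatrix(sols)
  expect_equal(nrow(m), 4L)

  # the four solutions as shift tuples over classes a..e
  shifts <- matrix(ex@peaks$position[m], nrow = nrow(m),
                   dimnames = list(NULL, colnames(m)))
  expected <- rbind(c(1.30, 2.52, 4.16, 7.47, 8.27),
                    c(2.52, 1.30, 4.16, 7.47, 8.27),
                    c(1.30, 2.52, 4.16, 8.27, 7.47),
                    c(2.52, 1.30, 4.16, 8.27, 7.47))
  keyed <- function(x) sort(apply(x, 1, paste, collapse = "|"))
  expect_equal(keyed(shifts), keyed(expected))

  cons <- consensusDyads(sols)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$delta, 4.16)
  expect_equal(ex@classLabels[cons$class], "c")
})

test_that("degenerate problems enumerate correctly", {
  one <- assignmentProblem(2, 3.1, 2)
  expect_equal(nrow(solutionMatrix(enumerateAssignments(one))), 1L)

  # three singleton classes over three unit peaks: all 3! permutations
  three <- assignmentProblem(rep(1, 3), c(1, 2, 3), rep(1, 3))
  m <- solutionMatrix(enumerateAssignments(three))
  expect_equal(nrow(m), 6L)
  expect_equal(m, oracleEnumerate(three))

  # symmetry: benzene is one class on one peak; 1 solution, never 6!
  benzLike <- assignmentProblem(6, 7.26, 6)
  expect_equal(nrow(solutionMatrix(enumerateAssignments(benzLike))), 1L)

  # impossible integral split: no solutions, empty consensus
  none <- assignmentProblem(c(2, 2), c(1, 2), c(3, 1))
  sols <- enumerateAssignments(none)
  expect_equal(nrow(solutionMatrix(sols)), 0L)
  expect_equal(nrow(consensusDyads(sols)), 0L)
})

test_that("branch-and-bound equals exhaustive enumeration on random problems", {
  withr::local_seed(20)
  for (i in 1:60) {
    pr <- randomProblem(maxClasses = 8L, maxPeaks = 5L)
    expect_identical(solutionMatrix(enumerateAssignments(pr)),
                     oracleEnumerate(pr),
                     label = sprintf("problem %d", i))
  }
})

test_that("adding a shift constraint never adds solutions", {
  withr::local_seed(21)
  for (i in 1:30) {
    pr <- randomProblem(constrain = FALSE)
    base <- solutionMatrix(enumerateAssignments(pr))
    k <- length(pr@classSizes)
    cl <- sample.int(k, 1)
    pr2 <- pr
    pr2@centers[cl] <- stats::runif(1, 0, 10)
    pr2@tolerances[cl] <- stats::runif(1, 0.05, 3)
    constrained <- solutionMatrix(enumerateAssignments(pr2))
    baseKeys <- apply(base, 1, paste, collapse = "|")
    conKeys <- apply(constrained, 1, paste, collapse = "|")
    expect_true(all(conKeys %in% baseKeys))
  }
})

test_that("consensus is order-invariant and handles disagreement", {
  ex <- fiveProtonExample()
  sols <- enumerateAssignments(ex)
  rev_ <- sols
  rev_@solutions <- sols@solutions[rev(seq_len(nrow(sols@solutions))), ]
  expect_equal(consensusDyads(rev_), consensusDyads(sols))

  # two solutions disagreeing on every class: empty consensus
  swap <- assignmentProblem(c(1, 1), c(2.0, 5.0), c(1, 1))
  s <- enumerateAssignments(swap)
  expect_equal(nrow(solutionMatrix(s)), 2L)
  expect_equal(nrow(consensusDyads(s)), 0L)
})

test_that("the solution cap yields an overflow status, not an exception", {
  # 8 singleton classes over 8 unit peaks: 8! = 40320 > 1000
  big <- assignmentProblem(rep(1, 8), seq(1, 8), rep(1, 8))
  sols <- enumerateAssignments(big, cap = 1000L)
  expect_equal(solutionStatus(sols), "overflow")
  expect_error(consensusDyads(sols), "overflow")
  # with a generous cap the same problem completes
  expect_equal(nrow(solutionMatrix(enumerateAssignments(big, cap = 50000L))),
               factorial(8))
})
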