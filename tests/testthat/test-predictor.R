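# Shift database, cascade prediction and tolerance formulas.

test_that("addObservation creates one entry per radius and deduplicates", {
  db <- shiftDatabase(2, 4)
  eth <- fixEthanol()
  p <- protonClasses(eth)[[1]][1]
  db <- addObservation(db, eth, p, 1.20, iteration = 0)
  expect_equal(nEntries(db), 3L)
  expect_equal(sort(shiftEntries(db)$radius), 2:4)

  # identical observation is a no-op
  db <- addObservation(db, eth, p, 1.20, iteration = 3)
  expect_equal(nEntries(db), 3L)

  # an equivalent proton of the same class, same shift: same codes, no-op
  p2 <- protonClasses(eth)[[1]][2]
  db <- addObservation(db, eth, p2, 1.20)
  expect_equal(nEntries(db), 3L)

  # same codes but different source molecule id: kept as extra entries
  db <- addObservation(db, eth, p, 1.20, id = "other")
  expect_equal(nEntries(db), 6L)
})

test_that("prediction cascades from rMax down and reports median/sd", {
  eth <- fixEthanol()
  p <- protonClasses(eth)[[1]][1]
  db <- shiftDatabase()

  expect_equal(predictionStatus(predictShift(db, eth, p)), "failed")

  # single entry matching at radius 4
  db1 <- addObservation(db, eth, p, 7.394)
  pred <- predictShift(db1, eth, p)
  expect_equal(predictedShift(pred), 7.394)
  expect_equal(matchCount(pred), 1L)
  expect_equal(radiusUsed(pred), 4L)
  expect_true(is.na(uncertainty(pred)))

  # matches only at radius 2: median and sample sd of {7.0, 7.2, 7.6}
  codes <- hoseCodes(eth, p, 2, 4)
  db2 <- addEntries(shiftDatabase(), data.frame(
    code = codes[["2"]], radius = 2L, delta = c(7.0, 7.2, 7.6),
    moleculeId = c("a", "b", "c"), iteration = 0L))
  pred2 <- predictShift(db2, eth, p)
  expect_equal(radiusUsed(pred2), 2L)
  expect_equal(predictedShift(pred2), 7.2)
  v <- c(7.0, 7.2, 7.6)
  expect_equal(uncertainty(pred2), sqrt(sum((v - mean(v))^2) / 2))
})

test_that("a larger-radius match shadows smaller radii entirely", {
  eth <- fixEthanol()
  p <- protonClasses(eth)[[1]][1]
  codes <- hoseCodes(eth, p, 2, 4)
  # absurd shifts at radius 2 must not influence the radius-4 hit
  db <- addEntries(shiftDatabase(), data.frame(
    code = c(codes[["4"]], codes[["2"]], codes[["2"]]),
    radius = c(4L, 2L, 2L), delta = c(1.25, 99, -99),
    moleculeId = c("x", "y", "z"), iteration = 0L))
  pred <- predictShift(db, eth, p)
  expect_equal(radiusUsed(pred), 4L)
  expect_equal(predictedShift(pred), 1.25)

  # repeat calls are byte-identical (pure function)
  expect_identical(predictShift(db, eth, p), pred)
})

test_that("median and sd agree with brute-force formulas on random multisets", {
  withr::local_seed(5)
  eth <- fixEthanol()
  p <- protonClasses(eth)[[1]][1]
  code2 <- hoseCodes(eth, p, 2, 4)[["2"]]
  for (i in 1:20) {
    v <- round(stats::runif(sample(2:100, 1), 0, 12), 3)
    db <- addEntries(shiftDatabase(), data.frame(
      code = code2, radius = 2L, delta = v,
      moleculeId = paste0("m", seq_along(v)), iteration = 0L))
    pred <- predictShift(db, eth, p)
    s <- sort(v); n <- length(s)
    oracleMedian <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(predictedShift(pred), oracleMedian)
    expect_equal(uncertainty(pred), sqrt(sum((v - mean(v))^2) / (n - 1)))
    expect_equal(matchCount(pred), n)
  }
})

test_that("scaled uncertainty follows epsilon * (1 + m^(-I/2))", {
  expect_equal(scaledUncertainty(0.1, 4, 2), 0.125)
  expect_equal(scaledUncertainty(0.2, 9, 0), 0.4)    # factor 2 at iteration 0
  expect_error(scaledUncertainty(0.1, 1, 2), "m >= 2")
  # strictly decreasing in I, approaching epsilon from above
  vals <- vapply(0:12, function(I) scaledUncertainty(0.1, 3, I), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0.1))
  expect_equal(vals[13], 0.1, tolerance = 1e-2)
})

test_that("assignment tolerance: 3x scaled uncertainty with 20 ppm fallback", {
  mk <- function(eps, m) new("ShiftPrediction", delta = 5, epsilon = eps,
                             m = as.integer(m), radiusUsed = 4L, status = "ok")
  cfg <- learnerConfig()
  expect_equal(assignmentTolerance(mk(NA_real_, 1), I = 0, cfg), 20)
  expect_equal(assignmentTolerance(mk(NA_real_, 1), I = 9, cfg), 20)
  expect_equal(assignmentTolerance(mk(0.1, 4), I = 2, cfg), 0.375)
  # degenerate epsilon hits the floor instead of locking out all peaks
  expect_equal(assignmentTolerance(mk(0, 5), I = 1, cfg), cfg$toleranceFloor)
  # stricter low-match threshold variant: two matches also fall back
  cfg3 <- learnerConfig(lowMatchThreshold = 3)
  expect_equal(assignmentTolerance(mk(0.1, 2), I = 1, cfg3), 20)
  expect_equal(assignmentTolerance(mk(0.1, 2), I = 1, cfg),
               3 * 0.1 * (1 + 2^(-0.5)))
  failed <- new("ShiftPrediction", delta = NA_real_, epsilon = NA_real_,
                m = 0L, radiusUsed = NA_integer_, status = "failed")
  expect_error(assignmentTolerance(failed, 1, cfg), "successful")
})

test_that("tolerance is non-increasing in iteration and in match count", {
  cfg <- learnerConfig()
  mk <- function(m) new("ShiftPrediction", delta = 5, epsilon = 0.3,
                        m = as.integer(m), radiusUsed = 3L, status = "ok")
  byI <- vapply(0:8, function(I) assignmentTolerance(mk(4), I, cfg), numeric(1))
  expect_true(all(diff(byI) <= 0))
  byM <- vapply(2:30, function(m) assignmentTolerance(mk(m), 2, cfg), numeric(1))
  expect_true(all(diff(byM) <= 0))
})

test_that("the TSV interchange round-trips the database", {
  eth <- fixEthanol()
  db <- shiftDatabase()
  for (cl in protonClasses(eth))
    db <- addObservation(db, eth, cl[1], round(stats::runif(1, 0, 10), 3))
  f <- tempfile(fileext = ".tsv")
  exportShiftTable(db, f)
  back <- importShiftTable(f)
  expect_equal(shiftEntries(back), shiftEntries(db))
  # and lookups behave identically
  p <- protonClasses(eth)[[2]][1]
  expect_identical(predictShift(back, eth, p), predictShift(db, eth, p))
})
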