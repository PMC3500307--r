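test_that("branching times are the internal node ages, descending", {
  tr <- parseNewick(text = "((A:1,B:1):1,C:2):0;")
  expect_equal(unname(branchingTimes(tr)), c(2, 1))
  poly <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2):0;")
  expect_error(branchingTimes(poly), "polytom")
  tr2 <- simBDTree(0.3, 0.05, age = 10, seed = 5)
  expect_length(branchingTimes(tr2), ape::Ntip(tr2) - 1)
  expect_equal(unname(branchingTimes(tr2)[1]), unname(max(nodeAges(tr2))))
})

test_that("the piecewise likelihood reduces to the constant-rate closed
           form", {
  ## the printed toy times under fixed rates
  expect_equal(bdLoglik(c(2, 1), 0.3, 0.1, rho = 1),
               constantRateBDOracle(c(2, 1), 0.3, 0.1, 1),
               tolerance = 1e-9)
  ## random draws over rates, sampling fraction and synthetic times
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    la <- runif(1, 0.05, 0.5); mu <- runif(1, 0, 0.9) * la
    rho <- runif(1, 0.2, 1)
    times <- sort(runif(n - 1, 0.05, 40), decreasing = TRUE)
    expect_equal(bdLoglik(times, la, mu, rho = rho),
                 constantRateBDOracle(times, la, mu, rho),
                 tolerance = 1e-9)
  }
})

test_that("input validation rejects impossible models", {
  expect_error(bdLoglik(c(2, 1), 0, 0.1), "positive")
  expect_error(bdLoglik(c(2, 1), c(0.3, 0.2), 0.1, shiftTimes = 1), "per epoch")
  expect_error(bdLoglik(c(2, 1), 0.3, 0.1, rho = 0), "rho")
  expect_error(bdLoglik(c(2, 1), c(0.3, 0.2, 0.1), c(0.1, 0.1, 0.1),
                        shiftTimes = c(2, 1)), "increasing")
})

test_that("a shift with identical rates collapses to the constant model", {
  times <- sort(runif(30, 0.1, 25), decreasing = TRUE)
  for (s in c(1, 5, 12)) {
    expect_equal(bdLoglik(times, c(0.31, 0.31), c(0.12, 0.12),
                          shiftTimes = s, rho = 0.7),
                 bdLoglik(times, 0.31, 0.12, rho = 0.7),
                 tolerance = 1e-10)
  }
})

test_that("the Yule maximum-likelihood rate matches the analytic estimator", {
  for (s in 1:3) {
    tr <- simBDTree(0.25, 0, age = 15, seed = 10 + s)
    times <- branchingTimes(tr)
    n <- ape::Ntip(tr)
    laHat <- unname((n - 2) / (2 * times[1] + sum(times[-1])))
    num <- stats::optimize(function(la) bdLoglik(times, la, 0, rho = 1),
                           c(0.01, 2), maximum = TRUE, tol = 1e-10)
    expect_equal(num$maximum, laHat, tolerance = 1e-6)
  }
})

test_that("likelihood is invariant to tip labels and child rotation", {
  tr <- simBDTree(0.4, 0.1, age = 8, seed = 77)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  shuf <- tr; shuf$tip.label <- sample(tr$tip.label)
  for (t in list(rot, shuf))
    expect_equal(bdLoglik(branchingTimes(t), 0.4, 0.1, rho = 0.8),
                 bdLoglik(branchingTimes(tr), 0.4, 0.1, rho = 0.8),
                 tolerance = 1e-12)
})

test_that("fitted likelihood is non-decreasing in the number of shifts", {
  tr <- simBDTree(0.3, 0.05, age = 18, seed = 8)
  fit <- fitShifts(tr, maxShifts = 2, gridStep = 2, rho = 1, seed = 3,
                   critValues = 1e9)   # force the scan to continue
  expect_true(all(diff(fit@table$logLik) >= -1e-8))
  expect_error(fitShifts(parseNewick(text = "(A:1,B:1);"), rho = 1),
               "10 tips")
})

test_that("constant-rate trees mostly select zero shifts", {
  acc <- 0
  for (s in 1:10) {
    tr <- simBDTree(0.22, 0.05, age = 22, seed = 900 + s)
    if (ape::Ntip(tr) < 10) next
    fit <- fitShifts(tr, maxShifts = 1, gridStep = 1, rho = 1, seed = s)
    if (fit@kSelected == 0L) acc <- acc + 1
  }
  expect_gte(acc, 8)
})

test_that("a strong simulated shift is detected and labelled increase", {
  tr <- simBDTree(c(0.35, 0.1), 0, age = 28, shiftTimes = 8, seed = 424)
  fit <- fitShifts(tr, maxShifts = 1, gridStep = 0.5, rho = 1, seed = 2)
  expect_equal(fit@kSelected, 1L)
  expect_equal(fit@shifts$direction, "increase")
  expect_lt(abs(fit@shifts$time - 8), 2.5)
})

test_that("the window-constrained test is a fixed-shift fit at a point
           window and is null-calibrated", {
  tr <- simBDTree(0.3, 0.05, age = 24, seed = 61)
  times <- branchingTimes(tr)
  res <- constrainedShiftTest(tr, rho = 1, window = c(10, 10), seed = 4)
  direct <- primdiv:::bdFitRates(times, 10, 1, nStarts = 3, seed = 4)
  expect_equal(res$shiftTime, 10)
  expect_equal(res$logLik <- res$deltaLnL +
                 primdiv:::bdFitRates(times, numeric(0), 1,
                                      seed = 4)$logLik,
               direct$logLik, tolerance = 1e-4)
  expect_gte(res$deltaLnL, 0)
  expect_error(constrainedShiftTest(tr, window = c(30, 40)), "window")
  ## null behavior: small median improvement on constant-rate trees
  deltas <- vapply(1:8, function(s) {
    tr <- simBDTree(0.3, 0.05, age = 24, seed = 700 + s)
    constrainedShiftTest(tr, rho = 1, window = c(10, 12), gridStep = 1,
                         seed = s)$deltaLnL
  }, numeric(1))
  expect_lt(median(deltas), 2)
})

test_that("a shift inside the window is detected with power", {
  hits <- 0
  for (s in 1:8) {
    tr <- simBDTree(c(0.3, 0.15), 0, age = 26, shiftTimes = 10, seed = 80 + s)
    res <- constrainedShiftTest(tr, rho = 1, window = c(9.5, 10.5),
                                gridStep = 0.5, seed = s)
    if (res$decision == "shift") hits <- hits + 1
  }
  expect_gte(hits, 6)
})
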