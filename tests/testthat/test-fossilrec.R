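test_that("occurrence pruning follows the species/indeterminate rules", {
  ## all species-level records pass through (merged per species)
  sp <- data.frame(genus = c("Aa", "Bb"), species = c("x", "y"),
                   first_ma = c(10, 20), last_ma = c(5, 15))
  pr <- pruneOccurrences(sp)
  expect_equal(nrow(pr), 2)
  expect_true(all(pr$rank == "species"))

  ## a genus with only indeterminate records collapses to one
  ## pseudo-species spanning them
  ind <- data.frame(genus = "Cc", species = c("", "", ""),
                    first_ma = c(40, 38, 35), last_ma = c(38, 33, 30))
  pr <- pruneOccurrences(ind)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$first_ma, 40)
  expect_equal(pr$last_ma, 30)
  expect_equal(pr$rank, "indet")

  ## determinate records suppress indeterminate ones in the same genus
  mix <- data.frame(genus = "Dd", species = c("z", "", ""),
                    first_ma = c(10, 42, 41), last_ma = c(5, 40, 39))
  pr <- pruneOccurrences(mix)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$taxon, "Dd z")

  ## missing ages are skipped with a warning, and pruning is idempotent
  bad <- rbind(sp, data.frame(genus = "Ee", species = "w",
                              first_ma = NA, last_ma = 3))
  expect_warning(pr <- pruneOccurrences(bad), "skipped")
  expect_equal(attr(pr, "nSkipped"), 1)
  again <- pruneOccurrences(data.frame(genus = pr$taxon,
                                       species = ifelse(pr$rank == "species",
                                                        "a", ""),
                                       first_ma = pr$first_ma,
                                       last_ma = pr$last_ma))
  expect_equal(again$first_ma, pr$first_ma)
  expect_equal(again$last_ma, pr$last_ma)
})

test_that("standing diversity is the inclusive range-through count", {
  expect_equal(standingDiversity(data.frame(first_ma = numeric(0),
                                            last_ma = numeric(0)),
                                 c(0, 10, 50)), c(0L, 0L, 0L))
  one <- data.frame(first_ma = 10, last_ma = 5)
  expect_equal(standingDiversity(one, 7), 1L)
  expect_equal(standingDiversity(one, 12), 0L)
  expect_equal(standingDiversity(one, 5), 1L)   # boundary inclusive
  expect_equal(standingDiversity(one, 10), 1L)

  ## brute-force scan oracle on random ranges
  set.seed(9)
  ranges <- data.frame(last_ma = runif(100, 0, 50))
  ranges$first_ma <- ranges$last_ma + runif(100, 0, 20)
  for (t in runif(20, 0, 60)) {
    brute <- sum(vapply(seq_len(100), function(i)
      ranges$first_ma[i] >= t && t >= ranges$last_ma[i], logical(1)))
    expect_equal(standingDiversity(ranges, t), brute)
  }
})

test_that("interval rates are per-lineage log ratios with a telescoping
           identity", {
  expect_equal(intervalRate(10, 10, 5), 0)
  expect_equal(intervalRate(10, 20, 5), log(2) / 5)
  expect_true(is.na(intervalRate(0, 10, 5)))
  expect_error(intervalRate(10, 20, 0), "positive")
  expect_equal(intervalRate(10, 20, 5, method = "arithmetic"), 10 / 50)

  ## rates reconstruct the final count from the initial one
  counts <- c(12, 20, 7, 15, 15, 30)
  dts <- c(5, 5, 10, 5, 5)
  r <- intervalRate(counts[-6], counts[-1], dts)
  expect_equal(counts[1] * exp(sum(r * dts)), counts[6])
})

test_that("timetree interval rates come from the LTT curve", {
  tr2 <- parseNewick(text = "(A:1,B:1);")
  rs <- timetreeIntervalRates(tr2, c(2, 0))
  expect_equal(rs$rate, log(2) / 2)    # 1 lineage above the root, 2 below
  expect_error(timetreeIntervalRates(tr2, c(0, 2)), "decreasing")

  ## boundaries older than the root give missing rates
  rs2 <- timetreeIntervalRates(tr2, c(5, 3, 0))
  expect_true(is.na(rs2$rate[1]))

  ## Yule tree: per-interval rates scatter around lambda
  la <- 0.3
  rates <- unlist(lapply(1:15, function(s) {
    tr <- simBDTree(la, 0, age = 15, seed = 130 + s)
    timetreeIntervalRates(tr, seq(12, 0, by = -4))$rate
  }))
  expect_lt(abs(mean(rates, na.rm = TRUE) - la), 0.06)
})

test_that("rate-series correlation is Pearson with pairwise deletion", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compareRateSeries(x, x), 1)
  expect_equal(compareRateSeries(x, -2 * x + 7), -1)
  ## symmetry and location/scale invariance
  set.seed(2)
  a <- rnorm(11); b <- rnorm(11)
  expect_equal(compareRateSeries(a, b), compareRateSeries(b, a))
  expect_equal(compareRateSeries(2 * a + 3, b), compareRateSeries(a, b))
  ## NA pairs are dropped; degenerate input reported as NA
  a2 <- a; a2[4] <- NA
  expect_equal(compareRateSeries(a2, b),
               stats::cor(a[-4], b[-4]))
  expect_warning(r0 <- compareRateSeries(rep(1, 5), b[1:5]), "variance")
  expect_true(is.na(r0))
  expect_error(compareRateSeries(a, b[1:5]), "equal length")
  expect_error(compareRateSeries(c(1, NA, NA, NA, 2), c(1, NA, NA, NA, 2)),
               "3 complete pairs")
})

test_that("a planted extinction pulse shows in the diversity curve", {
  ## target curve: plateau of 40 species dropping to 15 at 34 Ma
  target <- data.frame(age = 55:1,
                       count = ifelse(55:1 > 34, 40, 15))
  occ <- simFossilRanges(target, erosion = 0.05, seed = 99)
  pr <- pruneOccurrences(occ)
  curve <- diversityCurve(pr, ages = seq(55, 1, by = -1))
  before <- curve$count[curve$age == 36]
  after <- curve$count[curve$age == 30]
  expect_gte(before - after, 20)     # the planted drop (25) is visible
})

test_that("the plotting helpers run and return their curves", {
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  tr <- simBDTree(0.3, 0.05, age = 15, seed = 3)
  curve <- plotLTT(tr, shifts = data.frame(time = 5,
                                           direction = "increase"))
  expect_equal(curve$lineages[curve$age == 0], ape::Ntip(tr))
  ranges <- data.frame(first_ma = c(40, 30, 20), last_ma = c(30, 10, 0),
                       group = c("a", "a", "b"))
  total <- plotDiversityCurve(ranges, ages = seq(45, 0, -5),
                              highlight = 33.9)
  expect_equal(total$count[total$age == 25], 1L)
})
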