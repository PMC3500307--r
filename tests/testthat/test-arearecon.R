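primateSys <- areaSystem(c("Africa", "Madagascar", "Asia", "NewWorld"), 2)

test_that("state enumeration counts and ordering are as defined", {
  expect_length(enumerateStates(primateSys), 10)           # C(4,1)+C(4,2)
  expect_length(enumerateStates(areaSystem(letters[1:6], 2)), 21)
  expect_length(enumerateStates(areaSystem(letters[1:4], 4)), 15)  # 2^4-1
  st <- enumerateStates(primateSys)
  ## cardinality-then-bitmask order
  sizes <- vapply(st, function(m) length(rangeAreas(primateSys, m)),
                  integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_error(areaSystem("one"), "between 2 and 16")
})

test_that("the MAC cost is the symmetric difference and a metric", {
  asia <- areaRange(primateSys, "Asia")
  af <- areaRange(primateSys, "Africa")
  mad <- areaRange(primateSys, "Madagascar")
  asAf <- areaRange(primateSys, c("Asia", "Africa"))
  expect_equal(macCost(asia, asia), 0L)
  expect_equal(macCost(asia, asAf), 1L)
  expect_equal(macCost(asAf, mad), 3L)     # two losses plus one gain
  expect_error(macCost(asia, 0L), "non-empty")
  ## symmetry and triangle inequality on random triples
  st <- unname(enumerateStates(primateSys))
  set.seed(8)
  for (i in 1:50) {
    x <- sample(st, 3)
    expect_equal(macCost(x[1], x[2]), macCost(x[2], x[1]))
    expect_lte(macCost(x[1], x[3]), macCost(x[1], x[2]) + macCost(x[2], x[3]))
  }
})

test_that("Sankoff reconstruction equals exhaustive enumeration", {
  ## unanimous coding: zero changes everywhere
  tr <- parseNewick(text = "((A:1,B:1):1,C:2):0;")
  r0 <- macReconstruct(tr, list(A = "Asia", B = "Asia", C = "Asia"),
                       primateSys)
  expect_equal(minTotalChanges(r0), 0L)
  expect_true(all(vapply(nodeStates(r0), identical, logical(1), "Asia")))
  expect_equal(r0@gainsRange, c(0L, 0L))
  expect_equal(r0@lossesRange, c(0L, 0L))
  expect_error(macReconstruct(tr, list(A = "Asia", B = "Asia"), primateSys),
               "uncoded")

  ## randomized brute-force equivalence, including gain/loss extremes
  for (s in 1:15) {
    inst <- randomMACInstance(sample(4:6, 1), primateSys, 6000 + s)
    r <- macReconstruct(inst$tree, inst$masks, primateSys)
    bf <- bruteForceMAC(inst$tree, inst$masks, primateSys)
    expect_equal(minTotalChanges(r), as.integer(bf[1]))
    expect_equal(r@gainsRange, as.integer(bf[2:3]))
    expect_equal(r@lossesRange, as.integer(bf[1] - bf[3:2]))
  }
})

test_that("MPR state sets contain exactly the states used by some optimum", {
  ## A-B cherry with an outgroup sharing A's area: path A-B costs 2, and
  ## the cherry node's optimal state is A's area only
  tr <- parseNewick(text = "((A:1,B:1):1,C:2):0;")
  r <- macReconstruct(tr, list(A = "Asia", B = "Africa", C = "Asia"),
                      primateSys)
  expect_equal(minTotalChanges(r), 2L)
  expect_equal(nodeStates(r)[["5"]], "Asia")
  ## verify MPR membership against enumeration on a random instance
  inst <- randomMACInstance(5, primateSys, 777)
  r <- macReconstruct(inst$tree, inst$masks, primateSys)
  st <- unname(enumerateStates(primateSys))
  lbl <- names(enumerateStates(primateSys))
  ntip <- ape::Ntip(inst$tree)
  for (node in (ntip + 1):(ntip + inst$tree$Nnode)) {
    inMPR <- vapply(seq_along(st), function(i) {
      ## clamp this node to state i by brute force
      best <- Inf
      asgGrid <- expand.grid(rep(list(st), inst$tree$Nnode))
      sel <- asgGrid[asgGrid[[node - ntip]] == st[i], , drop = FALSE]
      full <- cbind(matrix(inst$masks[inst$tree$tip.label], nrow(sel),
                           ntip, byrow = TRUE), as.matrix(sel))
      cost <- 0
      for (k in seq_len(nrow(inst$tree$edge))) {
        u <- full[, inst$tree$edge[k, 1]]; v <- full[, inst$tree$edge[k, 2]]
        cost <- cost + primdiv:::popcount(bitwXor(u, v))
      }
      min(cost) == minTotalChanges(r)
    }, logical(1))
    expect_setequal(nodeStates(r)[[as.character(node)]], lbl[inMPR])
  }
})

test_that("multifurcating trees are handled by the parsimony ops", {
  tr <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2):0;")
  r <- macReconstruct(tr, list(A = "Asia", B = "Asia", C = "Africa",
                               D = "Asia"), primateSys)
  expect_equal(minTotalChanges(r), 2L)
})

test_that("with singleton ranges MAC equals twice the Fitch score", {
  ## every change between single-area states is one gain plus one loss,
  ## so the MAC minimum doubles an independent Fitch implementation's count
  skip_if_not_installed("phangorn")
  sys1 <- areaSystem(c("Africa", "Madagascar", "Asia", "NewWorld"), 1)
  set.seed(12)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    areas <- sample(sys1@areaNames, n, replace = TRUE)
    masks <- stats::setNames(vapply(areas, function(a) areaRange(sys1, a),
                                    integer(1)), tr$tip.label)
    r <- macReconstruct(tr, masks, sys1)
    dat <- phangorn::phyDat(matrix(areas, ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = sys1@areaNames)
    expect_equal(minTotalChanges(r), 2L * phangorn::fitch(tr, dat))
  }
})

test_that("the DEC rate matrix obeys its defining rates and row sums", {
  sys2 <- areaSystem(c("A", "B"), 2)
  Q <- decRateMatrix(sys2, d = 0.3, e = 0.1)
  expect_equal(dim(Q), c(4, 4))                  # null, A, B, AB
  expect_equal(Q["A", "A+B"], 0.3)               # d * |S| with |S| = 1
  expect_equal(Q["A+B", "A"], 0.1)               # e per lost area
  expect_equal(Q["A", "0"], 0.1)                 # single area may go null
  expect_equal(unname(rowSums(Q)), rep(0, 4))
  expect_true(all(decRateMatrix(sys2, 0, 0) == 0))
  ## expansion rate scales with range size when allowed
  sys3 <- areaSystem(c("A", "B", "C"), 3)
  Q3 <- decRateMatrix(sys3, d = 0.2, e = 0)
  expect_equal(Q3["A+B", "A+B+C"], 0.4)          # two source areas
  ## matrix exponentials are stochastic
  set.seed(3)
  for (i in 1:5) {
    Q <- decRateMatrix(primateSys, runif(1, 0, 0.5), runif(1, 0, 0.3))
    for (t in c(0.1, 1, 10)) {
      P <- primdiv:::transitionFun(Q)(t)
      expect_equal(unname(rowSums(P)), rep(1, nrow(Q)), tolerance = 1e-9)
      expect_true(all(P >= 0))
    }
  }
})

test_that("the DEC likelihood matches limits and is rotation invariant", {
  tr <- parseNewick(text = "((A:1,B:1):1,C:2):0;")
  unan <- list(A = "Asia", B = "Asia", C = "Asia")
  ## d -> 0, e = 0, unanimous tips: likelihood -> root weight of that area
  ll <- decLoglik(tr, unan, primateSys, 1e-9, 0, condition = "none")
  expect_equal(ll, log(1 / 10), tolerance = 1e-6)
  ## genuinely unreachable coding with d = 0 gives -Inf, not an error
  far <- list(A = "Madagascar", B = "NewWorld", C = "Africa")
  expect_identical(decLoglik(tr, far, primateSys, 0, 0.01,
                             condition = "none"), -Inf)
  ## rotation of children leaves the likelihood unchanged
  rot <- parseNewick(text = "(C:2,(B:1,A:1):1):0;")
  tips <- list(A = "Asia", B = c("Africa", "Asia"), C = "Madagascar")
  expect_equal(decLoglik(tr, tips, primateSys, 0.05, 0.02),
               decLoglik(rot, tips, primateSys, 0.05, 0.02),
               tolerance = 1e-12)
  ## a tip coded beyond the range cap is refused with guidance
  wide <- list(A = c("Asia", "Africa", "Madagascar"), B = "Asia", C = "Asia")
  expect_error(decLoglik(tr, wide, primateSys, 0.1, 0.1), "maxRangeSize")
})

test_that("DEC fitting is no worse than a log-grid scan", {
  tr <- simBDTree(0.4, 0.1, age = 10, seed = 21)
  dec <- simDECTips(tr, 0.05, 0.02, primateSys, seed = 22)
  fit <- decFit(tr, dec$tips, primateSys, gridN = 6)
  g <- seq(log(1e-5), log(10), length.out = 20)
  gridBest <- max(outer(g, g, Vectorize(function(a, b)
    decLoglik(tr, dec$tips, primateSys, exp(a), exp(b)))))
  expect_gte(fit@logLik, gridBest - 1e-4)
})

test_that("degenerate unanimous coding drives d-hat to the boundary", {
  tr <- simBDTree(0.5, 0, age = 6, seed = 31)
  tips <- stats::setNames(rep(areaRange(primateSys, "Asia"),
                              ape::Ntip(tr)), tr$tip.label)
  fit <- decFit(tr, tips, primateSys, gridN = 5)
  expect_lt(fit@d, 1e-3)
})

test_that("node range windows cover the states the data support", {
  tr <- parseNewick(text = "((A:1,B:1):1,C:2):0;")
  unan <- list(A = "Asia", B = "Asia", C = "Asia")
  nr <- decNodeRanges(tr, unan, primateSys, 0.05, 0.02, window = 2)
  for (tab in nr) expect_equal(tab$state[1], "Asia")
  ## the best clamped likelihood never exceeds the unclamped total, and the
  ## clamped candidates decompose it
  eng <- primdiv:::decPruningEngine(
    tr, primdiv:::tipMasks(tr, unan, primateSys), primateSys, 0.05, 0.02)
  total <- eng()
  states <- seq_along(c(0L, unname(enumerateStates(primateSys))))[-1]
  clamped <- vapply(states, function(s) eng(4L, s), numeric(1))
  expect_lte(max(clamped), total + 1e-12)
  expect_equal(log(sum(exp(clamped - total))) + total, total,
               tolerance = 1e-9)
})

test_that("dispersal events are counted per gained area on each branch", {
  tr <- parseNewick(text = "((A:1,B:1):1,C:2):0;")
  sys <- primateSys
  asia <- areaRange(sys, "Asia")
  ## identical ranges everywhere: no events
  ranges <- rep(asia, 5)
  expect_equal(nrow(countDispersals(tr, ranges, sys)), 0)
  ## a parent-to-child gain of Africa is one event naming Africa
  ranges2 <- ranges
  ranges2[1] <- areaRange(sys, c("Asia", "Africa"))
  ev <- countDispersals(tr, ranges2, sys)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$area, "Africa")
  ## losses at cladogenesis are not dispersals
  ranges3 <- rep(asia, 5)
  ranges3[4] <- areaRange(sys, c("Asia", "Africa"))  # root widespread
  expect_equal(nrow(countDispersals(tr, ranges3, sys)), 0)
})

test_that("counting on the true simulated history matches its event log", {
  ## without extirpation each area is gained at most once per branch and
  ## never lost within it, so the counted events are exactly the logged
  ## gains of areas absent from the parent node's range (a re-gain of an
  ## area dropped at cladogenesis is range inheritance, not dispersal)
  for (s in 1:5) {
    tr <- simBDTree(0.5, 0, age = 8, seed = 50 + s)
    dec <- simDECTips(tr, 0.04, 0, primateSys, seed = 60 + s)
    ev <- countDispersals(tr, dec$nodeRanges, primateSys)
    log <- dec$dispersals
    inParent <- mapply(function(p, a)
      a %in% rangeAreas(primateSys, dec$nodeRanges[p]),
      log$parent, log$area)
    log <- log[!inParent, , drop = FALSE]
    expect_equal(ev[order(ev$child, ev$area), c("child", "area")],
                 log[order(log$child, log$area), c("child", "area")],
                 ignore_attr = TRUE)
  }
  ## with extirpation a logged gain may be undone later on the same branch,
  ## so counted events are a subset of logged ones
  tr <- simBDTree(0.5, 0, age = 8, seed = 56)
  dec <- simDECTips(tr, 0.05, 0.03, primateSys, seed = 66)
  ev <- countDispersals(tr, dec$nodeRanges, primateSys)
  key <- function(d) paste(d$child, d$area)
  expect_true(all(key(ev) %in% key(dec$dispersals)))
})
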