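## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: vectorized exhaustive enumeration for MAC
## parsimony, closed-form constant-rate expressions for the birth-death
## likelihood, ODE integration for DEC, and brute-force scans for
## range-through diversity.

## exhaustive minimum-change enumeration over all internal-state
## assignments; returns c(minTotal, minGains, maxGains)
bruteForceMAC <- function(tree, masks, sys) {
  st <- unname(enumerateStates(sys))
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  popc <- function(x) {
    n <- integer(length(x))
    while (any(x > 0L)) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
    n
  }
  asg <- as.matrix(expand.grid(rep(list(st), nint)))
  full <- cbind(matrix(masks[tree$tip.label], nrow(asg), ntip,
                       byrow = TRUE), asg)
  cost <- 0; gains <- 0
  for (k in seq_len(nrow(tree$edge))) {
    u <- full[, tree$edge[k, 1]]; v <- full[, tree$edge[k, 2]]
    cost <- cost + popc(bitwXor(u, v))
    gains <- gains + popc(bitwAnd(v, bitwNot(u)))
  }
  mn <- min(cost)
  opt <- gains[cost == mn]
  c(mn, min(opt), max(opt))
}

## constant-rate reconstructed birth-death log-likelihood, written directly
## from the closed-form sampled-survival expressions
constantRateBDOracle <- function(times, la, mu, rho) {
  r <- la - mu
  uc <- function(t) rho * r / (rho * la + (la * (1 - rho) - mu) * exp(-r * t))
  qc <- function(t) uc(t)^2 * exp(-r * t) / rho
  x1 <- max(times)
  rest <- times[-which.max(times)]
  2 * log(qc(x1)) - 2 * log(uc(x1)) + sum(log(la) + log(qc(rest)))
}

## DEC log-likelihood of a symmetric 2-tip tree by numerical integration of
## the state master equation (deSolve), unconditioned
decTwoTipODEOracle <- function(tipA, tipB, t, sys, d, e) {
  states <- c(0L, unname(enumerateStates(sys)))
  ns <- length(states)
  Q <- decRateMatrix(sys, d, e)
  idx <- stats::setNames(seq_len(ns), as.character(states))
  integrate1 <- function(tip) {
    L0 <- as.numeric(states == tip)
    f <- function(s, y, p) list(as.numeric(Q %*% y))
    deSolve::ode(L0, c(0, t), f, NULL, rtol = 1e-11, atol = 1e-13)[2, -1]
  }
  LA <- integrate1(tipA); LB <- integrate1(tipB)
  scenPairs <- function(S) {
    areas <- Filter(function(b) bitwAnd(S, b) > 0L, bitwShiftL(1L, 0:15))
    if (length(areas) == 1) return(list(c(S, S)))
    out <- list()
    for (b in areas) {
      rest <- bitwAnd(S, bitwNot(b))
      out <- c(out, list(c(b, S), c(S, b), c(b, rest), c(rest, b)))
    }
    unique(out)
  }
  Lroot <- vapply(states, function(S) {
    if (S == 0L) return(0)
    sc <- scenPairs(S)
    mean(vapply(sc, function(p) LA[idx[[as.character(p[1])]]] *
                  LB[idx[[as.character(p[2])]]], numeric(1)))
  }, numeric(1))
  log(sum(Lroot[-1]) / (ns - 1))
}

## random coded instance for MAC tests
randomMACInstance <- function(nTips, sys, seed) {
  set.seed(seed)
  tr <- ape::rtree(nTips)
  st <- unname(enumerateStates(sys))
  masks <- stats::setNames(sample(st, nTips, replace = TRUE), tr$tip.label)
  list(tree = tr, masks = masks)
}
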