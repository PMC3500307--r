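#' @include arearecon-mac.R
NULL

## Dispersal-extinction-cladogenesis (DEC) likelihood with bounded range
## size: anagenetic range evolution along branches (dispersal rate d per
## source area per Myr, extirpation rate e per occupied area per Myr) by
## matrix exponentiation, discrete range-inheritance scenarios at
## speciation, and maximum-likelihood estimation of (d, e).

#' DEC anagenetic rate matrix
#'
#' States are the null range followed by [enumerateStates()]. Dispersal adds
#' area `a` to range `S` at rate `d * |S|` (one route per occupied source
#' area, uniform dispersal multipliers) provided `|S| + 1` does not exceed
#' the range-size cap; extirpation removes each occupied area at rate `e`
#' (a single-area range decays to the absorbing null range). Rows sum to 0.
#'
#' @param sys an [AreaSystem-class].
#' @param d dispersal rate per source area per Myr.
#' @param e extirpation rate per occupied area per Myr.
#' @return square rate matrix with dimnames; first state is `"0"` (null).
#' @export
decRateMatrix <- function(sys, d, e) {
  if (d < 0 || e < 0) stop("rates must be non-negative")
  states <- c(0L, unname(enumerateStates(sys)))
  ns <- length(states)
  Q <- matrix(0, ns, ns,
              dimnames = list(c("0", rangeLabel(sys, states[-1])),
                              c("0", rangeLabel(sys, states[-1]))))
  sizes <- popcount(states)
  idx <- setNames(seq_len(ns), as.character(states))
  for (i in seq_len(ns)) {
    S <- states[i]
    if (S == 0L) next                       # null is absorbing
    for (a in seq_len(nAreas(sys))) {
      bit <- bitwShiftL(1L, a - 1L)
      if (bitwAnd(S, bit) == 0L) {          # dispersal gain of a
        tgt <- bitwOr(S, bit)
        j <- idx[as.character(tgt)]
        if (!is.na(j)) Q[i, j] <- Q[i, j] + d * sizes[i]
      } else {                              # extirpation loss of a
        tgt <- bitwAnd(S, bitwNot(bit))
        Q[i, idx[as.character(tgt)]] <- e
      }
    }
    Q[i, i] <- -sum(Q[i, -i])
  }
  Q
}

## transition-probability factory: eigendecomposition fast path with
## Matrix::expm fallback when the reconstruction is poor
transitionFun <- function(Q) {
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  useEigen <- FALSE
  if (!is.null(eg) && all(is.finite(Mod(eg$values)))) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      P1 <- Re(eg$vectors %*% diag(exp(eg$values)) %*% Vi)
      ref <- as.matrix(Matrix::expm(Q))
      useEigen <- max(abs(P1 - ref)) < 1e-9
    }
  }
  if (useEigen) {
    V <- eg$vectors; lam <- eg$values
    function(t) {
      if (t == 0) return(diag(nrow(Q)))
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      if (t == 0) return(diag(nrow(Q)))
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

## cladogenetic inheritance scenarios for a parent range mask:
## size-1 ranges are inherited identically by both daughters; larger ranges
## split as ({a}, S), (S, {a}), ({a}, S\{a}), (S\{a}, {a}) for each a in S
## (6 scenarios for a 2-area range), with equal weights.
decScenarios <- function(S) {
  bits <- Filter(function(b) bitwAnd(S, b) > 0L,
                 bitwShiftL(1L, 0:15))
  if (length(bits) == 1L) return(list(list(S, S)))
  out <- list()
  for (b in bits) {
    rest <- bitwAnd(S, bitwNot(b))
    out <- c(out, list(list(b, S), list(S, b), list(b, rest),
                       list(rest, b)))
  }
  unique(out)
}

## precompute the pruning machinery for one (tree, coding, system); returns
## a closure evaluating the log-likelihood, optionally with one internal
## node clamped to a single state
decPruningEngine <- function(tree, masks, sys, d, e,
                             rootPrior = c("uniform", "sizeNormalized")) {
  rootPrior <- match.arg(rootPrior)
  Q <- decRateMatrix(sys, d, e)
  states <- c(0L, unname(enumerateStates(sys)))
  ns <- length(states)
  stateIdx <- setNames(seq_len(ns), as.character(states))
  Pt <- transitionFun(Q)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- childrenList(tree)
  po <- postorderNodes(tree)
  edgeLen <- numeric(nn)
  edgeLen[tree$edge[, 2]] <- tree$edge.length
  Plist <- vector("list", nn)
  for (v in tree$edge[, 2]) Plist[[v]] <- Pt(edgeLen[v])
  ## scenario bookkeeping per parent state: matrix of (left idx, right idx)
  scen <- lapply(states, function(S) {
    if (S == 0L) return(NULL)
    sc <- decScenarios(S)
    cbind(l = vapply(sc, function(x) stateIdx[[as.character(x[[1]])]],
                     integer(1)),
          r = vapply(sc, function(x) stateIdx[[as.character(x[[2]])]],
                     integer(1)))
  })
  tipL <- matrix(0, ntip, ns)
  for (i in seq_len(ntip)) {
    if (popcount(masks[i]) > sys@maxRangeSize)
      stop("tip '", tree$tip.label[i], "' is coded with more areas than ",
           "maxRangeSize allows; raise maxRangeSize or recode the tip")
    tipL[i, stateIdx[[as.character(masks[i])]]] <- 1
  }
  allowed <- which(states != 0L)
  prior <- rep(0, ns)
  if (rootPrior == "uniform") {
    prior[allowed] <- 1 / length(allowed)
  } else {
    ## equal weight per range-size class, shared among ranges of that size
    sz <- popcount(states[allowed])
    w <- 1 / table(sz)[as.character(sz)]
    prior[allowed] <- as.numeric(w / sum(w))
  }
  survTip <- c(0, rep(1, ns - 1))         # any non-null state at a tip
  function(clampNode = NULL, clampState = NULL, survival = FALSE) {
    L <- matrix(NA_real_, nn, ns)
    logScale <- 0
    up <- matrix(NA_real_, nn, ns)        # likelihood above each child edge
    for (i in seq_len(ntip))
      up[i, ] <- Plist[[i]] %*% (if (survival) survTip else tipL[i, ])
    for (node in po) {
      ch <- kids[[node]]
      l1 <- up[ch[1], ]; l2 <- up[ch[2], ]
      Lv <- numeric(ns)
      for (s in seq_len(ns)) {
        sc <- scen[[s]]
        if (is.null(sc)) next
        Lv[s] <- sum(l1[sc[, "l"]] * l2[sc[, "r"]]) / nrow(sc)
      }
      if (!is.null(clampNode) && node == clampNode) {
        keepv <- Lv[clampState]
        Lv[] <- 0
        Lv[clampState] <- keepv
      }
      m <- max(Lv)
      if (m <= 0) return(-Inf)
      Lv <- Lv / m
      logScale <- logScale + log(m)
      L[node, ] <- Lv
      if (node != ntip + 1L) up[node, ] <- Plist[[node]] %*% Lv
    }
    lik <- sum(prior * L[ntip + 1L, ])
    if (lik <= 0) return(-Inf)
    log(lik) + logScale
  }
}

#' DEC log-likelihood of tip ranges on a chronogram
#'
#' Felsenstein pruning over the DEC state space with per-branch transition
#' probabilities from [decRateMatrix()] by matrix exponentiation. At
#' cladogenesis a single-area parent range is inherited identically by both
#' daughters; a two-area range `{a,b}` splits into one of the six scenarios
#' `({a},{b})`, `({b},{a})`, `({a},{a,b})`, `({a,b},{a})`, `({b},{a,b})`,
#' `({a,b},{b})` with equal weight. The root state is weighted uniformly
#' over allowed non-null ranges.
#'
#' @param tree a binary ultrametric `phylo`.
#' @param tips tip coding as in [macReconstruct()]; tip ranges must respect
#'   `maxRangeSize`.
#' @param sys an [AreaSystem-class].
#' @param d,e DEC rates (per Myr).
#' @param rootPrior root weighting; `"uniform"` (default) over allowed
#'   non-null ranges.
#' @param condition `"nonNull"` (default) renormalizes by the probability
#'   that no lineage is ever absorbed into the null range (computed by a
#'   second pruning with unconstrained non-null tips), so the likelihood is
#'   conditioned on the clade's survival in some area - without this the
#'   extirpation rate is systematically pulled toward zero; `"none"` is the
#'   unconditioned likelihood.
#' @return the log-likelihood; `-Inf` (not an error) when the data have
#'   zero probability, e.g. discordant tips with `d = 0`.
#' @export
decLoglik <- function(tree, tips, sys, d, e, rootPrior = "uniform",
                      condition = c("nonNull", "none")) {
  condition <- match.arg(condition)
  masks <- tipMasks(tree, tips, sys)
  engine <- decPruningEngine(tree, masks, sys, d, e, rootPrior)
  ll <- engine()
  if (condition == "nonNull" && is.finite(ll))
    ll <- ll - engine(survival = TRUE)
  ll
}

#' DECFit: maximum-likelihood DEC parameter estimates
#'
#' @slot d,e estimated rates (per Myr).
#' @slot logLik maximized log-likelihood.
#' @slot convergence optimizer convergence flag (0 = converged).
#' @slot sys the [AreaSystem-class] used.
#' @export
setClass("DECFit",
         representation(d = "numeric", e = "numeric", logLik = "numeric",
                        convergence = "integer", sys = "AreaSystem"))

setMethod("show", "DECFit", function(object) {
  cat(sprintf("DEC fit: d = %.4g, e = %.4g (per Myr), lnL = %.4f\n",
              object@d, object@e, object@logLik))
  if (object@convergence != 0)
    cat("  warning: optimizer did not converge; grid-best values reported\n")
})

#' Maximum-likelihood DEC rates
#'
#' Bounded quasi-Newton optimization of [decLoglik()] in log-parameter
#' space, started from a coarse log-grid scan; if the optimizer fails or
#' ends below the best grid point, the grid optimum is returned with a
#' warning.
#'
#' @param tree,tips,sys as in [decLoglik()].
#' @param gridN per-axis size of the log-grid scan used for starting values
#'   and as a safety net.
#' @param lower,upper rate bounds for the search.
#' @param condition passed to [decLoglik()].
#' @return a [DECFit-class] object.
#' @export
decFit <- function(tree, tips, sys, gridN = 8, lower = 1e-5, upper = 10,
                   condition = "nonNull") {
  masks <- tipMasks(tree, tips, sys)
  obj <- function(par) {
    ll <- decLoglik(tree, masks, sys, exp(par[1]), exp(par[2]),
                    condition = condition)
    if (!is.finite(ll)) 1e10 else -ll
  }
  g <- seq(log(lower), log(upper), length.out = gridN)
  gridVals <- outer(g, g, Vectorize(function(a, b) -obj(c(a, b))))
  best <- arrayInd(which.max(gridVals), dim(gridVals))
  start <- c(g[best[1]], g[best[2]])
  opt <- tryCatch(
    nlminb(start, obj, lower = log(lower) - 1e-9, upper = log(upper) + 1e-9),
    error = function(e) NULL)
  gridBest <- max(gridVals)
  if (is.null(opt) || -opt$objective < gridBest - 1e-8) {
    warning("DEC optimization did not converge; returning grid-scan optimum")
    return(new("DECFit", d = exp(start[1]), e = exp(start[2]),
               logLik = gridBest, convergence = 1L, sys = sys))
  }
  new("DECFit", d = exp(opt$par[1]), e = exp(opt$par[2]),
      logLik = -opt$objective, convergence = as.integer(opt$convergence),
      sys = sys)
}

#' Supported ancestral ranges per node
#'
#' For every internal node, each candidate range is clamped in turn and the
#' global log-likelihood recomputed; candidates within `window` log-units of
#' the unclamped optimum are reported, sorted by likelihood loss. The best
#' state's clamped likelihood equals the unclamped [decLoglik()] when the
#' node's likelihood surface is dominated by one state, and is never above
#' it.
#'
#' @param tree,tips,sys as in [decLoglik()].
#' @param d,e DEC rates (typically from [decFit()]).
#' @param window log-likelihood window (default 2 log-units).
#' @return named list (by ape internal node number) of data.frames with
#'   columns `state` and `deltaLnL`.
#' @export
decNodeRanges <- function(tree, tips, sys, d, e, window = 2.0) {
  masks <- tipMasks(tree, tips, sys)
  engine <- decPruningEngine(tree, masks, sys, d, e)
  states <- c(0L, unname(enumerateStates(sys)))
  labels <- c("0", rangeLabel(sys, states[-1]))
  cand <- which(states != 0L)
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  res <- lapply(nodes, function(node) {
    ll <- vapply(cand, function(s) engine(node, s), numeric(1))
    delta <- max(ll) - ll
    keep <- which(delta <= window & is.finite(ll))
    out <- data.frame(state = labels[cand[keep]], deltaLnL = delta[keep],
                      stringsAsFactors = FALSE)
    out[order(out$deltaLnL, out$state), , drop = FALSE]
  })
  setNames(res, nodes)
}

#' Count dispersal events from per-node best ranges
#'
#' An event is recorded on branch `(u, v)` for each area present in `v`'s
#' range but absent from `u`'s; losses at cladogenesis are range
#' inheritance, not dispersal. Node ranges are given one per node (the
#' reconstruction's best state, ties broken by the reported order, i.e. the
#' lexicographically smallest optimal range).
#'
#' @param tree a `phylo`.
#' @param nodeRanges integer bitmask vector indexed by ape node number
#'   (tips then internals); tip entries are the observed ranges.
#' @param sys an [AreaSystem-class] (for labelling).
#' @return data.frame with columns `parent`, `child`, `area`; zero rows when
#'   ranges are identical everywhere.
#' @export
countDispersals <- function(tree, nodeRanges, sys) {
  ev <- list()
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    gained <- bitwAnd(nodeRanges[v], bitwNot(nodeRanges[u]))
    if (gained > 0L)
      for (a in rangeAreas(sys, gained))
        ev[[length(ev) + 1L]] <- data.frame(parent = u, child = v, area = a,
                                            stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(parent = integer(0), child = integer(0),
                      area = character(0), stringsAsFactors = FALSE))
  do.call(rbind, ev)
}
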