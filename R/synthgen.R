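## Seeded generators for every input the pipeline consumes: birth-death
## chronograms (with optional rate shifts and rho-sampling), tip ranges
## under the DEC process, fossil species ranges around a true diversity
## curve, and sparse supermatrix occupancy patterns. Each generator draws
## from its own named pseudo-random stream derived from the master seed, so
## adding a generator never perturbs existing fixtures.

## derive a deterministic substream seed (< 2^31) from seed + stream name
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * (seq_along(utf8ToInt(stream)) + 31))
  as.integer((as.numeric(seed) * 48271 + h * 2654435761) %% 2147483647)
}

## set the RNG inside a function without disturbing the caller's stream;
## returns a restorer to call on exit
localRNG <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a reconstructed birth-death chronogram
#'
#' Forward-time simulation from the root split under piecewise-constant
#' speciation/extinction rates, followed by uniform rho-sampling of extant
#' tips and pruning to the reconstructed tree of sampled tips. When `n` is
#' given instead of `age`, the simulation stops the moment the extant
#' lineage count first reaches `n` (before sampling).
#'
#' @param lambda,mu per-epoch rates per lineage per Myr, youngest epoch
#'   first, one more than `length(shiftTimes)`.
#' @param rho sampling fraction at present (each extant tip kept
#'   independently).
#' @param age stop age: root age in Ma (exclusive with `n`).
#' @param n stop tip count (exclusive with `age`).
#' @param shiftTimes strictly increasing shift ages in Ma. With an `age`
#'   stop these are absolute ages; with an `n` stop rates are indexed from
#'   the start of the simulation (ages unknown in advance), so constant
#'   rates are recommended there.
#' @param seed integer master seed; identical inputs give identical trees.
#' @param maxRetries resimulation attempts when the clade dies or fewer
#'   than 2 tips are sampled.
#' @return a `phylo` with attributes `"log"` (data.frame of true speciation
#'   event ages, reconstructed or not) and `"nExtant"` (extant count before
#'   sampling).
#' @export
simBDTree <- function(lambda, mu = 0, rho = 1, age = NULL, n = NULL,
                      shiftTimes = numeric(0), seed = NULL,
                      maxRetries = 1000) {
  if (is.null(age) == is.null(n)) stop("supply exactly one of 'age' and 'n'")
  if (length(lambda) != length(shiftTimes) + 1)
    stop("need one lambda per epoch")
  mu <- rep_len(mu, length(lambda))
  if (any(lambda <= 0) || any(mu < 0)) stop("invalid rates")
  if (!is.null(seed)) {
    restore <- localRNG(deriveSeed(seed, "bdtree"))
    on.exit(restore(), add = TRUE)
  }
  for (try in seq_len(maxRetries)) {
    sim <- if (!is.null(age)) bdForwardAge(lambda, mu, shiftTimes, age)
           else bdForwardN(lambda[1], mu[1], n)
    if (is.null(sim)) next
    extant <- sim$tips
    if (length(extant) < 2) next
    keep <- extant[runif(length(extant)) <= rho]
    if (length(keep) < 2) next
    tr <- parseNewick(text = sim$newick)
    tr <- pruneToTaxa(tr, keep)
    attr(tr, "log") <- sim$log
    attr(tr, "nExtant") <- length(extant)
    return(tr)
  }
  stop("all ", maxRetries, " simulation attempts went extinct or left ",
       "fewer than 2 sampled tips; lower mu or raise rho")
}

## forward simulation from 2 lineages at the root, stopping at total age T.
## Lineages are stored as records (parent, birth forward-time); rate epochs
## are piecewise in age (T - t).
bdForwardAge <- function(lambda, mu, shiftTimes, T) {
  ## epoch boundaries in forward time, oldest first
  bnd <- sort(T - shiftTimes)
  bnd <- c(bnd[bnd > 0 & bnd < T], T)
  cap <- 1024L
  parent <- rep(NA_integer_, cap); birth <- numeric(cap)
  death <- rep(NA_real_, cap)
  nrec <- 2L
  alive <- integer(cap); alive[1:2] <- 1:2; nAlive <- 2L
  logEv <- numeric(0)
  t <- 0
  repeat {
    ageNow <- T - t
    ep <- bdEpoch(ageNow - 1e-12, shiftTimes)  # epoch of current age
    la <- lambda[ep]; m <- mu[ep]
    nextBnd <- bnd[bnd > t + 1e-12][1]
    rate <- nAlive * (la + m)
    dt <- if (rate > 0) rexp(1, rate) else Inf
    if (t + dt >= nextBnd) {
      t <- nextBnd
      if (t >= T - 1e-12) break
      next
    }
    t <- t + dt
    k <- sample.int(nAlive, 1)
    i <- alive[k]
    if (runif(1) <= la / (la + m)) {
      if (nrec + 2L > cap) {
        cap <- cap * 2L
        parent <- c(parent, rep(NA_integer_, cap / 2))
        birth <- c(birth, numeric(cap / 2))
        death <- c(death, rep(NA_real_, cap / 2))
        alive <- c(alive, integer(cap / 2))
      }
      parent[nrec + 1:2] <- i
      birth[nrec + 1:2] <- t
      death[i] <- t
      alive[k] <- nrec + 1L
      nAlive <- nAlive + 1L
      alive[nAlive] <- nrec + 2L
      nrec <- nrec + 2L
      logEv <- c(logEv, T - t)
    } else {
      death[i] <- t
      alive[k] <- alive[nAlive]
      nAlive <- nAlive - 1L
      if (!nAlive) return(NULL)
    }
  }
  finishForwardSim(parent[seq_len(nrec)], birth[seq_len(nrec)],
                   death[seq_len(nrec)], alive[seq_len(nAlive)], T, logEv)
}

## forward simulation with constant rates stopping when extant count hits n
bdForwardN <- function(la, m, n) {
  parent <- c(NA_integer_, NA_integer_)
  birth <- c(0, 0)
  death <- c(NA_real_, NA_real_)
  alive <- c(1L, 2L)
  logEv <- numeric(0)
  t <- 0
  guard <- 0
  while (length(alive) < n) {
    guard <- guard + 1
    if (guard > 100 * n + 10000) return(NULL)
    t <- t + rexp(1, length(alive) * (la + m))
    i <- alive[sample.int(length(alive), 1)]
    if (runif(1) <= la / (la + m)) {
      parent <- c(parent, i, i)
      birth <- c(birth, t, t)
      death <- c(death, NA_real_, NA_real_)
      death[i] <- t
      alive <- c(setdiff(alive, i), length(parent) - 1L, length(parent))
      logEv <- c(logEv, t)    # forward time; converted below
    } else {
      death[i] <- t
      alive <- setdiff(alive, i)
      if (!length(alive)) return(NULL)
    }
  }
  res <- finishForwardSim(parent, birth, death, alive, t, t - logEv)
  res
}

## assemble the full (extinct tips included) Newick and prune bookkeeping
finishForwardSim <- function(parent, birth, death, alive, T, logAges) {
  death[is.na(death)] <- T
  kids <- split(seq_along(parent), parent)
  label <- paste0("t", seq_along(parent))
  nwk <- function(i) {
    ch <- kids[[as.character(i)]]
    len <- format(death[i] - birth[i], digits = 12)
    if (is.null(ch)) paste0(label[i], ":", len)
    else paste0("(", nwk(ch[1]), ",", nwk(ch[2]), "):", len)
  }
  txt <- paste0("(", nwk(1L), ",", nwk(2L), ");")
  list(newick = txt, tips = label[alive],
       log = data.frame(age = sort(logAges, decreasing = TRUE)))
}

## constant-rate tree conditioned on tip count (rejection; exact for
## n <= 50, else within 10%) and root age (by rescaling); used for type-I
## calibration
simBDTreeConditioned <- function(nTips, rootAge, lambda, mu = 0, rho = 1,
                                 seed = NULL, maxRetries = 2000) {
  if (!is.null(seed)) {
    restore <- localRNG(deriveSeed(seed, "bdcond"))
    on.exit(restore(), add = TRUE)
  }
  tolBand <- if (nTips <= 50) 0 else ceiling(0.1 * nTips)
  ## expected age at which a supercritical process reaches nTips
  guessAge <- if (lambda > mu) log(nTips / 2) / (lambda - mu) else rootAge
  for (try in seq_len(maxRetries)) {
    sim <- bdForwardAge(lambda, mu, numeric(0), guessAge)
    if (is.null(sim)) next
    keep <- sim$tips[runif(length(sim$tips)) <= rho]
    if (abs(length(keep) - nTips) > tolBand) next
    tr <- pruneToTaxa(parseNewick(text = sim$newick), keep)
    sc <- rootAge / max(branchingTimes(tr))
    tr$edge.length <- tr$edge.length * sc
    return(tr)
  }
  stop("failed to hit the target tip count in ", maxRetries, " attempts")
}

#' Simulate tip ranges under the DEC process
#'
#' Gillespie simulation of dispersal/extirpation along every branch under
#' [decRateMatrix()], with cladogenetic daughter ranges drawn uniformly
#' from the equal-weight inheritance scenarios. A branch whose range hits
#' the null set is resimulated (bounded retries).
#'
#' @param tree a `phylo` chronogram.
#' @param d,e DEC rates per Myr.
#' @param sys an [AreaSystem-class].
#' @param seed integer master seed.
#' @param rootState optional bitmask for the root range; drawn uniformly
#'   from the allowed states when `NULL`.
#' @param maxRetries per-branch resimulation attempts on null absorption.
#' @return list with `tips` (named bitmask vector), `nodeRanges` (bitmask
#'   per ape node number, tips included) and `dispersals` (data.frame
#'   `parent`, `child`, `area`, `age` of every anagenetic gain).
#' @export
simDECTips <- function(tree, d, e, sys, seed = NULL, rootState = NULL,
                       maxRetries = 100) {
  if (!is.null(seed)) {
    restore <- localRNG(deriveSeed(seed, "dectips"))
    on.exit(restore(), add = TRUE)
  }
  states <- unname(enumerateStates(sys))
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  age <- nodeAges(tree)
  kids <- childrenList(tree)
  nodeRange <- integer(nn)
  root <- ntip + 1L
  nodeRange[root] <- if (is.null(rootState))
    states[sample.int(length(states), 1)] else as.integer(rootState)
  disp <- list()
  evolveBranch <- function(S0, len, topAge) {
    for (try in seq_len(maxRetries)) {
      S <- S0; t <- 0; ev <- list()
      ok <- TRUE
      repeat {
        sz <- popcount(S)
        addable <- if (sz < sys@maxRangeSize)
          rangeAreas(sys, bitwAnd(bitwNot(S), 2^nAreas(sys) - 1L))
          else character(0)
        gainRate <- d * sz * length(addable)
        lossRate <- e * sz
        tot <- gainRate + lossRate
        if (tot <= 0) break
        t <- t + rexp(1, tot)
        if (t >= len) break
        if (runif(1) <= gainRate / tot) {
          a <- addable[sample.int(length(addable), 1)]
          ev[[length(ev) + 1L]] <- list(area = a, age = topAge - t)
          S <- bitwOr(S, areaRange(sys, a))
        } else {
          drop <- rangeAreas(sys, S)[sample.int(sz, 1)]
          S <- bitwAnd(S, bitwNot(areaRange(sys, drop)))
          if (S == 0L) { ok <- FALSE; break }
        }
      }
      if (ok) return(list(S = S, events = ev))
    }
    stop("branch repeatedly absorbed into the null range; lower e ",
         "relative to d")
  }
  ## preorder over internal nodes: draw cladogenetic scenario, evolve the
  ## two child branches
  for (node in rev(postorderNodes(tree))) {
    sc <- decScenarios(nodeRange[node])
    pick <- sc[[sample.int(length(sc), 1)]]
    ch <- kids[[node]]
    for (j in 1:2) {
      start <- as.integer(pick[[j]])
      len <- age[node] - age[ch[j]]
      res <- evolveBranch(start, len, age[node])
      nodeRange[ch[j]] <- res$S
      for (evt in res$events)
        disp[[length(disp) + 1L]] <-
          data.frame(parent = node, child = ch[j], area = evt$area,
                     age = evt$age, stringsAsFactors = FALSE)
    }
  }
  dispersals <- if (length(disp)) do.call(rbind, disp) else
    data.frame(parent = integer(0), child = integer(0),
               area = character(0), age = numeric(0),
               stringsAsFactors = FALSE)
  list(tips = setNames(nodeRange[seq_len(ntip)], tree$tip.label),
       nodeRanges = nodeRange, dispersals = dispersals)
}

#' Simulate fossil species ranges around a true diversity curve
#'
#' Builds a pool of true species durations whose range-through standing
#' diversity tracks a target curve (origination/extinction drawn at 1-Myr
#' steps to follow the curve), then erodes each duration into an observed
#' (first, last) pair and optionally converts records to genus-indeterminate
#' ones.
#'
#' @param curve data.frame with columns `age` (Ma, decreasing) and `count`
#'   (true standing diversity at that age).
#' @param erosion fraction in `[0, 1)`: observed first/last occurrences are
#'   drawn uniformly within the outer `erosion` fraction of the true
#'   duration at each end (0 = perfect preservation).
#' @param pIndet probability a species' record is logged as
#'   genus-indeterminate rather than species-level.
#' @param genusSize mean number of species per genus (geometric grouping).
#' @param seed integer master seed.
#' @return data.frame with columns `genus`, `species`, `first_ma`,
#'   `last_ma`, `rank` (`"species"`/`"indet"`); attributes `"trueRanges"`
#'   (the un-eroded durations) and `"nIndet"`.
#' @export
simFossilRanges <- function(curve, erosion = 0.1, pIndet = 0,
                            genusSize = 3, seed = NULL) {
  if (!is.null(seed)) {
    restore <- localRNG(deriveSeed(seed, "fossil"))
    on.exit(restore(), add = TRUE)
  }
  curve <- curve[order(-curve$age), ]
  first <- numeric(0); last <- numeric(0)
  open <- integer(0)        # indices of currently extant species
  for (i in seq_len(nrow(curve))) {
    target <- curve$count[i]
    ageI <- curve$age[i]
    while (length(open) < target) {
      first <- c(first, ageI); last <- c(last, NA_real_)
      open <- c(open, length(first))
    }
    while (length(open) > target) {
      j <- open[sample.int(length(open), 1)]
      last[j] <- ageI
      open <- setdiff(open, j)
    }
  }
  last[is.na(last)] <- min(curve$age)
  nsp <- length(first)
  dur <- first - last
  obsFirst <- first - runif(nsp, 0, erosion) * dur
  obsLast <- last + runif(nsp, 0, erosion) * dur
  bad <- obsFirst < obsLast
  if (any(bad)) { obsFirst[bad] <- first[bad]; obsLast[bad] <- last[bad] }
  genus <- paste0("Genus", cumsum(runif(nsp) < 1 / genusSize) + 1)
  indet <- runif(nsp) < pIndet
  out <- data.frame(genus = genus,
                    species = ifelse(indet, "", paste0("sp", seq_len(nsp))),
                    first_ma = obsFirst, last_ma = obsLast,
                    rank = ifelse(indet, "indet", "species"),
                    stringsAsFactors = FALSE)
  attr(out, "trueRanges") <- data.frame(first_ma = first, last_ma = last)
  attr(out, "nIndet") <- sum(indet)
  out
}

#' Simulate a sparse supermatrix (FASTA + partition file)
#'
#' Generates per-cell occupancy by independent Bernoulli draws (optionally
#' with a block of high-completeness "backbone" taxa emulating exemplar
#' species with many sequenced loci), fills present cells with random
#' nucleotides and absent cells with gaps, and optionally writes FASTA and
#' RAxML-style partition files that round-trip through
#' [readOccupancyMatrix()].
#'
#' @param nTaxa number of taxa.
#' @param lociLengths named integer vector of locus lengths (names become
#'   partition names).
#' @param fillProb probability a taxon has a given locus; the default
#'   emulates the roughly one-third occupancy of published primate
#'   supermatrices.
#' @param backboneTaxa number of taxa given occupancy probability
#'   `backboneProb` across all loci (default 0: plain Bernoulli fill).
#' @param backboneProb fill probability for backbone taxa.
#' @param mask optional logical nTaxa x nLoci matrix overriding the random
#'   fill entirely (planted occupancy).
#' @param fastaFile,partitionFile optional output paths.
#' @param seed integer master seed.
#' @return invisibly, a list with `sequences` (named character vector),
#'   `partitions` (data.frame `name`, `start`, `end`, 1-based inclusive)
#'   and `mask` (the realized occupancy matrix).
#' @export
simOccupancyMatrix <- function(nTaxa, lociLengths, fillProb = 0.314,
                               backboneTaxa = 0, backboneProb = 0.95,
                               mask = NULL, fastaFile = NULL,
                               partitionFile = NULL, seed = NULL) {
  if (!is.null(seed)) {
    restore <- localRNG(deriveSeed(seed, "occupancy"))
    on.exit(restore(), add = TRUE)
  }
  nl <- length(lociLengths)
  if (is.null(names(lociLengths)))
    names(lociLengths) <- paste0("locus", seq_len(nl))
  if (is.null(mask)) {
    mask <- matrix(runif(nTaxa * nl) < fillProb, nTaxa, nl)
    if (backboneTaxa > 0)
      mask[seq_len(min(backboneTaxa, nTaxa)), ] <-
        matrix(runif(min(backboneTaxa, nTaxa) * nl) < backboneProb,
               min(backboneTaxa, nTaxa), nl)
  }
  taxa <- sprintf("taxon%03d", seq_len(nTaxa))
  seqs <- vapply(seq_len(nTaxa), function(i) {
    paste(vapply(seq_len(nl), function(j) {
      L <- lociLengths[j]
      if (mask[i, j])
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
      else strrep("-", L)
    }, character(1)), collapse = "")
  }, character(1))
  names(seqs) <- taxa
  ends <- cumsum(lociLengths)
  parts <- data.frame(name = names(lociLengths),
                      start = c(1L, utils::head(ends, -1) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  if (!is.null(fastaFile))
    writeLines(paste0(">", taxa, "\n", seqs), fastaFile)
  if (!is.null(partitionFile))
    writeLines(sprintf("DNA, %s = %d-%d", parts$name, parts$start,
                       parts$end), partitionFile)
  invisible(list(sequences = seqs, partitions = parts, mask = mask))
}
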