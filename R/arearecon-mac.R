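## Minimum-area-change (MAC) parsimony: ancestral ranges are non-empty area
## sets of bounded size, the cost of an edge is the number of area gains plus
## losses (symmetric difference), and reconstruction is Sankoff dynamic
## programming over the enumerated state space. Branch lengths are ignored.

#' AreaSystem: a set of geographic areas with bounded ancestral range size
#'
#' @slot areaNames character vector of area names (2-16 areas).
#' @slot maxRangeSize largest range cardinality allowed at internal nodes
#'   (the primate analyses use 2).
#' @export
setClass("AreaSystem",
         representation(areaNames = "character", maxRangeSize = "integer"),
         validity = function(object) {
  n <- length(object@areaNames)
  if (n < 2 || n > 16) return("need between 2 and 16 areas")
  if (anyDuplicated(object@areaNames)) return("area names must be unique")
  if (object@maxRangeSize < 1 || object@maxRangeSize > n)
    return("maxRangeSize must lie in [1, n areas]")
  TRUE
})

#' Construct an AreaSystem
#'
#' @param areaNames character vector of area names.
#' @param maxRangeSize maximum range cardinality at internal nodes.
#' @return an [AreaSystem-class] object.
#' @examples
#' primateAreas <- areaSystem(c("Africa", "Madagascar", "Asia", "NewWorld"))
#' @export
areaSystem <- function(areaNames, maxRangeSize = 2) {
  new("AreaSystem", areaNames = areaNames,
      maxRangeSize = as.integer(maxRangeSize))
}

setMethod("show", "AreaSystem", function(object) {
  cat("AreaSystem:", paste(object@areaNames, collapse = ", "),
      "| max range size", object@maxRangeSize, "\n")
})

#' @describeIn AreaSystem-class number of areas
#' @param x an `AreaSystem`.
#' @export
nAreas <- function(x) length(x@areaNames)

#' Encode a set of area names as a range bitmask
#'
#' @param sys an [AreaSystem-class].
#' @param areas character vector of area names (or an integer bitmask passed
#'   through).
#' @return integer bitmask; bit i set means area i present.
#' @export
areaRange <- function(sys, areas) {
  if (is.numeric(areas)) return(as.integer(areas))
  idx <- match(areas, sys@areaNames)
  if (anyNA(areas) || anyNA(idx))
    stop("unknown area(s): ", paste(areas[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, idx - 1L))
}

#' Decode a range bitmask to area names
#' @param sys an [AreaSystem-class].
#' @param mask integer bitmask.
#' @return character vector of area names.
#' @export
rangeAreas <- function(sys, mask) {
  sys@areaNames[bitwAnd(bitwShiftR(mask, seq_len(nAreas(sys)) - 1L), 1L) == 1L]
}

popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

rangeLabel <- function(sys, mask)
  vapply(mask, function(m) paste(rangeAreas(sys, m), collapse = "+"),
         character(1))

#' Enumerate allowed ancestral range states
#'
#' All non-empty subsets of the areas with cardinality at most
#' `maxRangeSize`, ordered by cardinality then bitmask value.
#'
#' @param sys an [AreaSystem-class].
#' @return integer vector of bitmasks, named by `+`-joined area names.
#' @export
enumerateStates <- function(sys) {
  all <- seq_len(2^nAreas(sys) - 1L)
  keep <- all[popcount(all) <= sys@maxRangeSize]
  keep <- keep[order(popcount(keep), keep)]
  setNames(keep, rangeLabel(sys, keep))
}

#' MAC edge cost: area gains plus losses
#'
#' The symmetric difference cardinality between two ranges; a metric on
#' non-empty area sets.
#'
#' @param S,T integer bitmasks (non-empty).
#' @return integer change count.
#' @export
macCost <- function(S, T) {
  if (any(S == 0L) || any(T == 0L)) stop("ranges must be non-empty")
  popcount(bitwXor(as.integer(S), as.integer(T)))
}

#' Read a tip-to-area coding table
#'
#' CSV with columns `taxon,areas`, areas as semicolon-separated names.
#'
#' @param file path to the CSV.
#' @param sys an [AreaSystem-class] used to validate names.
#' @return named integer vector of bitmasks, one per taxon.
#' @export
readTipAreas <- function(file, sys) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "areas") %in% names(df)))
    stop("tip-area CSV needs columns 'taxon' and 'areas'")
  setNames(vapply(strsplit(df$areas, ";"),
                  function(a) areaRange(sys, trimws(a)), integer(1)),
           df$taxon)
}

## normalize a tips argument (named bitmask vector or list of area-name
## vectors) against a tree, erroring on uncoded tips
tipMasks <- function(tree, tips, sys) {
  if (is.list(tips))
    tips <- vapply(tips, function(a) areaRange(sys, a), integer(1),
                   USE.NAMES = TRUE)
  missing <- setdiff(tree$tip.label, names(tips))
  if (length(missing))
    stop("uncoded tip(s): ", paste(missing, collapse = ", "))
  masks <- as.integer(tips[tree$tip.label])
  if (any(masks == 0L)) stop("tip ranges must be non-empty")
  setNames(masks, tree$tip.label)
}

## children of every node from the edge matrix (handles multifurcations)
childrenList <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(nn)))
}

## postorder sequence of internal node numbers
postorderNodes <- function(tree) {
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  unique(ed[, 1])
}

#' MACResult: Sankoff reconstruction with change-count decomposition
#'
#' @slot minTotalChanges minimum total gains+losses over the tree.
#' @slot nodeStates list (by ape internal node number) of the range states,
#'   as `+`-joined area labels, attainable in at least one
#'   most-parsimonious reconstruction (MPR).
#' @slot gainsRange,lossesRange integer `(min, max)` of the gain and loss
#'   decomposition over all MPRs.
#' @slot sys the [AreaSystem-class] used.
#' @export
setClass("MACResult",
         representation(minTotalChanges = "integer", nodeStates = "list",
                        gainsRange = "integer", lossesRange = "integer",
                        sys = "AreaSystem"))

setMethod("show", "MACResult", function(object) {
  cat("MAC parsimony reconstruction:", object@minTotalChanges,
      "gains or losses of area\n")
  cat(sprintf("  gains %d-%d, losses %d-%d across all MPRs\n",
              object@gainsRange[1], object@gainsRange[2],
              object@lossesRange[1], object@lossesRange[2]))
  amb <- sum(vapply(object@nodeStates, length, integer(1)) > 1)
  cat("  ", length(object@nodeStates), "internal nodes;", amb,
      "ambiguous\n")
})

#' @describeIn MACResult-class minimum total change count
#' @param x a `MACResult`.
#' @export
minTotalChanges <- function(x) x@minTotalChanges

#' @describeIn MACResult-class per-node MPR state sets
#' @export
nodeStates <- function(x) x@nodeStates

#' Ancestral ranges by MAC parsimony
#'
#' Sankoff dynamic programming over [enumerateStates()] with the symmetric
#' difference cost [macCost()]. Branch lengths are ignored; multifurcations
#' are allowed. Tip observations may be area sets of any (non-zero) size;
#' internal states are capped at `maxRangeSize`. Per-node MPR sets contain
#' every state attainable in a globally minimal reconstruction, and the
#' gain/loss extremes over all MPRs are computed exactly by an augmented DP
#' (see [macChangeBounds()]).
#'
#' @param tree a `phylo`; only the topology is used.
#' @param tips named bitmask vector (see [areaRange()]) or named list of
#'   area-name vectors, one entry per tip.
#' @param sys an [AreaSystem-class].
#' @return a [MACResult-class] object.
#' @export
macReconstruct <- function(tree, tips, sys) {
  masks <- tipMasks(tree, tips, sys)
  states <- enumerateStates(sys)
  ns <- length(states)
  C <- outer(states, states, function(a, b) popcount(bitwXor(a, b)))
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- childrenList(tree)
  up <- matrix(NA_real_, nn, ns)     # subtree cost given node state
  minterm <- vector("list", nn)      # per-node list of child min terms
  for (node in postorderNodes(tree)) {
    terms <- lapply(kids[[node]], function(ch) {
      if (ch <= ntip) popcount(bitwXor(states, masks[ch]))
      else apply(C + rep(up[ch, ], each = ns), 1, min)
    })
    minterm[[node]] <- terms
    up[node, ] <- Reduce(`+`, terms)
  }
  root <- ntip + 1L
  minTotal <- min(up[root, ])
  ## down pass: cost of the rest of the tree given node state
  down <- matrix(NA_real_, nn, ns)
  down[root, ] <- 0
  for (node in rev(postorderNodes(tree))) {   # preorder over internals
    ch <- kids[[node]]
    for (j in seq_along(ch)) {
      chj <- ch[j]
      if (chj <= ntip) next
      rest <- down[node, ] + up[node, ] - minterm[[node]][[j]]
      down[chj, ] <- apply(C + rest, 2, min)  # rest recycles over rows (s)
    }
  }
  tol <- 1e-9
  mpr <- lapply((ntip + 1L):nn, function(node) {
    tot <- up[node, ] + down[node, ]
    names(states)[tot <= minTotal + tol]
  })
  bounds <- macChangeBounds(tree, masks, sys)
  new("MACResult", minTotalChanges = as.integer(minTotal),
      nodeStates = setNames(mpr, (ntip + 1L):nn),
      gainsRange = bounds$gains, lossesRange = bounds$losses, sys = sys)
}

#' Gain/loss extremes over all most-parsimonious reconstructions
#'
#' Every MPR attains the same total change count but may decompose it
#' differently into gains (`|child \\ parent|`) and losses
#' (`|parent \\ child|`). The extremes are computed exactly by dynamic
#' programming over (state, subtree cost) pairs carrying the min and max
#' gains achievable at each cost, so trees of any size are handled without
#' enumerating MPRs.
#'
#' @param tree a `phylo` (topology only).
#' @param tips tip coding as in [macReconstruct()].
#' @param sys an [AreaSystem-class].
#' @return list with integer `gains = c(min, max)`, `losses = c(min, max)`
#'   and `minTotalChanges`.
#' @export
macChangeBounds <- function(tree, tips, sys) {
  masks <- tipMasks(tree, tips, sys)
  states <- enumerateStates(sys)
  ns <- length(states)
  C <- outer(states, states, function(a, b) popcount(bitwXor(a, b)))
  G <- outer(states, states, function(a, b) popcount(bitwAnd(b, bitwNot(a))))
  ntip <- ape::Ntip(tree)
  kids <- childrenList(tree)
  ## quick Sankoff for the cap
  capFit <- sankoffMin(tree, masks, states, C)
  cap <- capFit$minTotal
  nc <- cap + 1L
  ## gmin[[node]] / gmax[[node]]: ns x nc matrices of min/max gains in the
  ## node's subtree given (node state, subtree cost); Inf/-Inf unreachable
  gmin <- vector("list", ntip + tree$Nnode)
  gmax <- vector("list", ntip + tree$Nnode)
  for (node in postorderNodes(tree)) {
    accMin <- matrix(c(rep(0, ns), rep(Inf, ns * (nc - 1))), ns, nc)
    accMax <- matrix(c(rep(0, ns), rep(-Inf, ns * (nc - 1))), ns, nc)
    for (ch in kids[[node]]) {
      if (ch <= ntip) {
        ec <- popcount(bitwXor(states, masks[ch]))
        eg <- popcount(bitwAnd(masks[ch], bitwNot(states)))
        tmin <- matrix(Inf, ns, nc); tmax <- matrix(-Inf, ns, nc)
        ok <- ec <= cap
        tmin[cbind(which(ok), ec[ok] + 1L)] <- eg[ok]
        tmax[cbind(which(ok), ec[ok] + 1L)] <- eg[ok]
      } else {
        cmin <- gmin[[ch]]; cmax <- gmax[[ch]]
        tmin <- matrix(Inf, ns, nc); tmax <- matrix(-Inf, ns, nc)
        for (s in seq_len(ns)) for (t in seq_len(ns)) {
          ec <- C[s, t]
          if (ec >= nc) next
          reach <- seq_len(nc - ec)
          tgt <- reach + ec
          tmin[s, tgt] <- pmin(tmin[s, tgt], cmin[t, reach] + G[s, t])
          tmax[s, tgt] <- pmax(tmax[s, tgt], cmax[t, reach] + G[s, t])
        }
      }
      ## convolve accumulated with this child's term over cost
      nAccMin <- matrix(Inf, ns, nc); nAccMax <- matrix(-Inf, ns, nc)
      for (c1 in seq_len(nc)) {
        fin1 <- is.finite(accMin[, c1])
        if (!any(fin1)) next
        for (c2 in seq_len(nc - c1 + 1L)) {
          tgt <- c1 + c2 - 1L
          v <- accMin[, c1] + tmin[, c2]
          nAccMin[, tgt] <- pmin(nAccMin[, tgt], v)
          v <- accMax[, c1] + tmax[, c2]
          nAccMax[, tgt] <- pmax(nAccMax[, tgt], v)
        }
      }
      accMin <- nAccMin; accMax <- nAccMax
    }
    gmin[[node]] <- accMin; gmax[[node]] <- accMax
  }
  root <- ntip + 1L
  gMin <- min(gmin[[root]][, nc])
  gMax <- max(gmax[[root]][, nc])
  list(gains = as.integer(c(gMin, gMax)),
       losses = as.integer(c(cap - gMax, cap - gMin)),
       minTotalChanges = as.integer(cap))
}

## minimal Sankoff up-pass returning the optimum total cost
sankoffMin <- function(tree, masks, states, C) {
  ns <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- childrenList(tree)
  up <- matrix(NA_real_, nn, ns)
  for (node in postorderNodes(tree)) {
    terms <- lapply(kids[[node]], function(ch) {
      if (ch <= ntip) popcount(bitwXor(states, masks[ch]))
      else apply(C + rep(up[ch, ], each = ns), 1, min)
    })
    up[node, ] <- Reduce(`+`, terms)
  }
  list(minTotal = as.integer(min(up[ntip + 1L, ])), up = up)
}
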