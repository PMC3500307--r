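## Chronogram I/O, node ages, lineage-through-time machinery, pruning and
## truncation. Trees are `ape::phylo` objects; ages are Ma before present,
## branch lengths Myr.

#' Parse a Newick chronogram
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' rooted, carries branch lengths, and round-trips through
#' [writeChronogram()] with lengths preserved to better than 1e-9.
#'
#' @param text a Newick string (terminated by `;`).
#' @param file alternatively, path to a Newick file; exactly one of `text`
#'   and `file` must be given.
#' @return an object of class `phylo`.
#' @seealso [nodeAges()], [assertUltrametric()]
#' @export
parseNewick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' and 'file'")
  if (!is.null(file)) {
    tr <- ape::read.tree(file = file)
  } else {
    if (!grepl(";", text, fixed = TRUE))
      stop("malformed Newick: no terminating ';' (offset ", nchar(text), ")")
    ## locate unbalanced parentheses before handing to the reader, so errors
    ## carry a character offset
    bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                         ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
    if (any(bal < 0))
      stop("malformed Newick: unbalanced ')' at character offset ",
           which(bal < 0)[1])
    if (bal[length(bal)] != 0)
      stop("malformed Newick: ", bal[length(bal)], " unclosed '(' at offset ",
           nchar(text))
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  }
  if (is.null(tr)) stop("malformed Newick: reader returned no tree")
  if (is.null(tr$edge.length))
    stop("Newick tree has no branch lengths; chronograms require them")
  if (anyNA(tr$edge.length))
    stop("Newick tree has missing branch lengths on ",
         sum(is.na(tr$edge.length)), " edge(s)")
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tr
}

#' Write a chronogram to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when written to file).
#' @export
writeChronogram <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Node ages of an ultrametric tree
#'
#' Ages are Ma before present: tips sit at (approximately) 0 and the root at
#' the tree depth. Tip ages are snapped to exactly 0 and internal ages to the
#' mean root-to-node distance so that downstream arithmetic is exact.
#'
#' @param tree a `phylo` object.
#' @param tol relative ultrametricity tolerance (fraction of root age).
#' @return named numeric vector of length `Ntip + Nnode`, indexed by ape node
#'   number; tip entries are named by tip label.
#' @export
nodeAges <- function(tree, tol = 1e-6) {
  assertUltrametric(tree, tol = tol)
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  T <- max(depth[seq_len(ntip)])
  age <- T - depth
  age[seq_len(ntip)] <- 0
  names(age) <- c(tree$tip.label, rep("", tree$Nnode))
  age
}

#' Check ultrametricity, with an informative failure
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance as a fraction of root age.
#' @return invisibly `TRUE`; errors listing the worst tip pair otherwise.
#' @export
assertUltrametric <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  d <- depth[seq_len(ntip)]
  T <- max(d)
  if (T <= 0) stop("tree has zero depth")
  if ((max(d) - min(d)) / T > tol) {
    iw <- which.min(d); ib <- which.max(d)
    stop(sprintf(paste0("tree is not ultrametric within relative tolerance ",
                        "%g: tip '%s' at depth %.6g vs tip '%s' at %.6g"),
                 tol, tree$tip.label[iw], d[iw], tree$tip.label[ib], d[ib]))
  }
  invisible(TRUE)
}

#' Branching times of a binary ultrametric tree, descending
#'
#' @param tree a `phylo` object; must be fully bifurcating.
#' @return numeric vector of the `Ntip - 1` internal-node ages (Ma),
#'   sorted oldest first (the first entry is the root age).
#' @export
branchingTimes <- function(tree) {
  if (!ape::is.binary(tree))
    stop("tree contains polytomies; diversification operations require a ",
         "fully bifurcating tree")
  age <- nodeAges(tree)
  sort(age[(ape::Ntip(tree) + 1L):length(age)], decreasing = TRUE)
}

#' Lineage-through-time curve
#'
#' Returns the reconstructed lineage count as a step function of age. At ages
#' in `(x_k+1, x_k)` between consecutive branching times the count is the
#' number of branching events at or older than the interval's old end, plus
#' one; at age 0 the count equals the number of tips.
#'
#' @param tree an ultrametric `phylo` object.
#' @return a data.frame with columns `age` (Ma, decreasing toward 0) and
#'   `lineages`; one row per branching event plus a terminal row at age 0.
#' @export
lttCurve <- function(tree) {
  age <- nodeAges(tree)
  bt <- sort(age[(ape::Ntip(tree) + 1L):length(age)], decreasing = TRUE)
  data.frame(age = c(bt, 0),
             lineages = c(seq_along(bt) + 1L, ape::Ntip(tree)))
}

#' Lineage count at an arbitrary age
#'
#' Number of reconstructed lineages crossing age `t`: 1 + the number of
#' branching events strictly older than `t`. Just below the root the count
#' is 2; above the root it is 1 (the single stem lineage).
#'
#' @param tree an ultrametric `phylo` object.
#' @param t age(s) in Ma.
#' @return integer vector of lineage counts.
#' @export
lineagesAt <- function(tree, t) {
  age <- nodeAges(tree)
  bt <- age[(ape::Ntip(tree) + 1L):length(age)]
  vapply(t, function(ti) sum(bt > ti) + 1L, integer(1))
}

#' Prune a chronogram to a taxon subset
#'
#' Retains the induced subtree on `keep`, suppressing degree-2 nodes (their
#' branch lengths are summed), so pairwise tip distances and root-to-tip
#' depths of retained taxa are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo`.
#' @export
pruneToTaxa <- function(tree, keep) {
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 taxa to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Truncate a chronogram at an age cutoff
#'
#' Removes all branching events younger than `cutoff`; each lineage crossing
#' the cutoff line becomes a single tip ending exactly at `cutoff` age (the
#' returned tree's tips sit at age 0 of the *truncated* timescale, i.e. its
#' depth is root age minus `cutoff`). The tip count equals the
#' lineage-through-time count at `cutoff`. Used to strip Pleistocene
#' branching (2.6 Ma) before shift analyses.
#'
#' @param tree an ultrametric `phylo` object.
#' @param cutoff age in Ma, `0 < cutoff < root age`.
#' @return a `phylo` whose tips represent lineages alive at `cutoff`;
#'   node ages of retained internal nodes are shifted by `-cutoff`.
#' @export
truncateAtAge <- function(tree, cutoff) {
  age <- nodeAges(tree)
  ntip <- ape::Ntip(tree)
  root <- max(age)
  if (cutoff <= 0 || cutoff >= root)
    stop("cutoff must lie strictly between 0 and the root age (",
         format(root), " Ma)")
  ## representative tip for each lineage crossing the cutoff: for every edge
  ## (parent older than cutoff, child at or younger), keep one descendant tip
  parentAge <- age[tree$edge[, 1]]
  childAge <- age[tree$edge[, 2]]
  crossing <- which(parentAge > cutoff & childAge <= cutoff)
  reps <- vapply(tree$edge[crossing, 2], function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    tips <- ape::extract.clade(tree, node)$tip.label
    tips[1]
  }, character(1))
  sub <- pruneToTaxa(tree, reps)
  ## trim terminal branches so every tip ends at the cutoff line
  subAge <- nodeAges(sub)
  term <- which(sub$edge[, 2] <= ape::Ntip(sub))
  newLen <- subAge[sub$edge[term, 1]] - cutoff
  if (any(newLen < 0)) stop("internal error: truncation produced a node ",
                            "younger than the cutoff")
  sub$edge.length[term] <- newLen
  sub
}
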