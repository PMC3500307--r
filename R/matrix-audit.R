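## Supermatrix occupancy auditing: which taxa have which loci in a sparse
## concatenated alignment, and the completeness statistics derived from it.

#' OccupancyMatrix: taxa-by-loci presence/length grid
#'
#' Per-cell counts of determined (non-gap, non-missing) characters for every
#' taxon x locus pair of a concatenated alignment. A taxon "has" a locus iff
#' its cell count is at least 1.
#'
#' @slot taxa character vector of taxon labels.
#' @slot loci data.frame with columns `name`, `start`, `end`: 0-based
#'   half-open column intervals tiling `[0, nColumns)`.
#' @slot cells integer matrix, taxa x loci, of determined-character counts.
#' @slot nColumns total alignment length in columns.
#' @export
setClass("OccupancyMatrix",
         representation(taxa = "character", loci = "data.frame",
                        cells = "matrix", nColumns = "integer"),
         validity = function(object) {
  msg <- character(0)
  lo <- object@loci
  if (!all(c("name", "start", "end") %in% names(lo)))
    msg <- c(msg, "loci must have columns name, start, end")
  else {
    o <- order(lo$start)
    if (any(lo$start[o] != c(0, lo$end[o][-nrow(lo)])))
      msg <- c(msg, "locus intervals must tile [0, nColumns) without gaps ",
               "or overlap")
    if (max(lo$end) != object@nColumns)
      msg <- c(msg, "locus intervals must end at nColumns")
    len <- lo$end - lo$start
    if (any(t(object@cells) > len))
      msg <- c(msg, "cell counts exceed locus length")
  }
  if (!identical(dim(object@cells),
                 c(length(object@taxa), nrow(lo))))
    msg <- c(msg, "cells must be |taxa| x |loci|")
  if (any(object@cells < 0)) msg <- c(msg, "cell counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OccupancyMatrix", function(object) {
  cat("OccupancyMatrix:", length(object@taxa), "taxa x", nrow(object@loci),
      "loci (", object@nColumns, "columns )\n")
  filled <- sum(object@cells)
  cat(sprintf("  %d of %d cells filled (%.1f%%)\n", filled,
              length(object@taxa) * object@nColumns,
              100 * filled / (length(object@taxa) * object@nColumns)))
})

#' @describeIn OccupancyMatrix-class taxon labels
#' @param x,object an `OccupancyMatrix`.
#' @export
taxa <- function(x) x@taxa

#' @describeIn OccupancyMatrix-class locus table (name, start, end; 0-based
#'   half-open)
#' @export
loci <- function(x) x@loci

#' @describeIn OccupancyMatrix-class taxa x loci determined-character counts
#' @export
cellCounts <- function(x) x@cells

#' Characters counted as missing when auditing occupancy
#'
#' Gaps, `?`, fully ambiguous IUPAC codes (`N`, `X`) and blanks are treated
#' as absent; partial ambiguity codes (R, Y, ...) count as determined.
#' @export
MISSING_CHARS <- c("-", "?", "N", "n", "X", "x", ".", " ")

#' Load an occupancy matrix from an alignment plus partition file
#'
#' Reads a FASTA or sequential NEXUS alignment and a RAxML-style partition
#' file (`DNA, name = start-end`, 1-based inclusive coordinates) and counts
#' determined characters per taxon and locus.
#'
#' @param alignment path to a FASTA (`.fa`/`.fasta`) or sequential NEXUS
#'   (`.nex`/`.nexus`) alignment, or a named character vector of equal-length
#'   sequences.
#' @param partitions path to a RAxML-style partition file, or a data.frame
#'   with columns `name`, `start`, `end` (1-based inclusive).
#' @param missingChars characters counted as absent; see [MISSING_CHARS].
#' @return an [OccupancyMatrix-class] object.
#' @export
readOccupancyMatrix <- function(alignment, partitions,
                                missingChars = MISSING_CHARS) {
  seqs <- if (is.character(alignment) && length(alignment) == 1 &&
              file.exists(alignment)) {
    readAlignmentFile(alignment)
  } else if (is.character(alignment) && !is.null(names(alignment))) {
    alignment
  } else stop("'alignment' must be a file path or a named character vector")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths range ", min(lens), "-",
         max(lens), "; all sequences must be equal length")
  nCol <- lens[1]
  parts <- if (is.data.frame(partitions)) partitions else
    readPartitionFile(partitions)
  if (any(parts$start < 1) || any(parts$end > nCol))
    stop("partition intervals fall outside the alignment (1-",
         nCol, ")")
  o <- order(parts$start)
  if (any(parts$start[o][-1] != parts$end[o][-nrow(parts)] + 1))
    stop("partition intervals must tile the alignment without overlap; ",
         "check intervals around column ",
         parts$start[o][which(parts$start[o][-1] !=
                                parts$end[o][-nrow(parts)] + 1)[1] + 1])
  ## per-column missingness, then per-locus determined counts
  charMat <- do.call(rbind, strsplit(unname(seqs), ""))
  present <- !(charMat %in% missingChars)
  dim(present) <- dim(charMat)
  cells <- vapply(seq_len(nrow(parts)), function(i)
    as.integer(rowSums(present[, parts$start[i]:parts$end[i], drop = FALSE])),
    integer(length(seqs)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = length(seqs))
  new("OccupancyMatrix", taxa = names(seqs),
      loci = data.frame(name = parts$name, start = parts$start - 1L,
                        end = parts$end, stringsAsFactors = FALSE),
      cells = cells, nColumns = as.integer(nCol))
}

readAlignmentFile <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) {
    lst <- ape::read.nexus.data(path)
    vapply(lst, function(x) paste(x, collapse = ""), character(1))
  } else {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readBStringSet(path)
      setNames(as.character(ss), names(ss))
    } else {
      ## seqinr-free fallback FASTA reader for odd installs
      lines <- readLines(path)
      hdr <- grepl("^>", lines)
      idx <- cumsum(hdr)
      nm <- sub("^>\\s*", "", lines[hdr])
      setNames(vapply(split(lines[!hdr], idx[!hdr]),
                      paste, character(1), collapse = ""), nm)
    }
  }
}

readPartitionFile <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  m <- regmatches(lines,
                  regexec("^[A-Za-z0-9]+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)",
                          lines))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad))
    stop("unparseable partition line(s): ",
         paste(utils::head(lines[bad], 3), collapse = " | "))
  data.frame(name = vapply(m, `[`, character(1), 2),
             start = as.integer(vapply(m, `[`, character(1), 3)),
             end = as.integer(vapply(m, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Occupancy summary statistics
#'
#' Computes the completeness statistics customarily reported for a
#' supermatrix: total and filled cell counts (a cell is one taxon x alignment
#' column), percent filled, mean determined nucleotides per taxon, per-locus
#' taxon counts (taxon completeness) and per-taxon locus counts (gene
#' completeness).
#'
#' @param m an [OccupancyMatrix-class] object.
#' @return a list of class `occupancySummary` with elements `nTaxa`,
#'   `nColumns`, `totalCells`, `filledCells`, `percentFilled`,
#'   `meanPerTaxon`, `taxaPerLocus` (+ `meanTaxaPerLocus`), `lociPerTaxon`
#'   (+ `meanLociPerTaxon`).
#' @export
occupancySummary <- function(m) {
  stopifnot(is(m, "OccupancyMatrix"))
  filled <- sum(as.numeric(m@cells))
  res <- occupancySummaryFromCounts(length(m@taxa), m@nColumns, filled)
  res$taxaPerLocus <- setNames(colSums(m@cells > 0), m@loci$name)
  res$meanTaxaPerLocus <- mean(res$taxaPerLocus)
  res$lociPerTaxon <- setNames(rowSums(m@cells > 0), m@taxa)
  res$meanLociPerTaxon <- mean(res$lociPerTaxon)
  res
}

#' Occupancy bookkeeping from bare counts
#'
#' The cell-count arithmetic of [occupancySummary()] exposed directly, for
#' auditing published matrix dimensions without the alignment in hand.
#'
#' @param nTaxa,nColumns matrix dimensions.
#' @param filledCells number of cells filled by determined nucleotides.
#' @return list of class `occupancySummary` (without per-locus/taxon detail).
#' @examples
#' s <- occupancySummaryFromCounts(372, 61199, 7140500)
#' s$totalCells      # 22766028
#' round(s$percentFilled, 1)   # 31.4
#' round(s$meanPerTaxon, 1)    # 19194.9
#' @export
occupancySummaryFromCounts <- function(nTaxa, nColumns, filledCells) {
  if (nTaxa <= 0 || nColumns <= 0) stop("matrix dimensions must be positive")
  total <- as.numeric(nTaxa) * as.numeric(nColumns)
  if (filledCells < 0 || filledCells > total)
    stop("filledCells must lie in [0, totalCells]")
  structure(list(nTaxa = nTaxa, nColumns = nColumns, totalCells = total,
                 filledCells = filledCells,
                 percentFilled = 100 * filledCells / total,
                 meanPerTaxon = filledCells / nTaxa),
            class = "occupancySummary")
}

#' @export
print.occupancySummary <- function(x, ...) {
  cat(sprintf("Supermatrix occupancy: %d taxa x %d columns = %s cells\n",
              x$nTaxa, x$nColumns, format(x$totalCells, big.mark = ",")))
  cat(sprintf("  filled: %s (%.1f%%); mean per taxon: %.1f\n",
              format(x$filledCells, big.mark = ","), x$percentFilled,
              x$meanPerTaxon))
  if (!is.null(x$meanTaxaPerLocus))
    cat(sprintf("  mean taxa per locus: %.1f; mean loci per taxon: %.1f\n",
                x$meanTaxaPerLocus, x$meanLociPerTaxon))
  invisible(x)
}

#' Sampling/completeness percentage
#'
#' `100 * sampled / total`, reported to one decimal (round half-up), the
#' convention used for taxon completeness figures such as 367/450 = 81.6%.
#'
#' @param sampled,total non-negative counts, `total > 0`.
#' @param digits decimals in the reported value.
#' @return the percentage, rounded.
#' @export
completenessFraction <- function(sampled, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(sampled < 0) || any(sampled > total))
    stop("sampled must lie in [0, total]")
  roundHalfUp(100 * sampled / total, digits)
}

## round half away from zero (R's round() is banker's rounding)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Taxa represented by exactly one locus
#'
#' @param m an [OccupancyMatrix-class] object.
#' @return data.frame with columns `taxon`, `locus`, ordered by taxon label;
#'   zero rows when no singletons exist.
#' @export
singletonReport <- function(m) {
  stopifnot(is(m, "OccupancyMatrix"))
  nloc <- rowSums(m@cells > 0)
  idx <- which(nloc == 1)
  if (!length(idx))
    return(data.frame(taxon = character(0), locus = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(
    taxon = m@taxa[idx],
    locus = m@loci$name[apply(m@cells[idx, , drop = FALSE], 1, which.max)],
    stringsAsFactors = FALSE)
  out[order(out$taxon), , drop = FALSE]
}
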