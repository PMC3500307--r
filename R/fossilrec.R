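## Fossil range-through standing diversity, per-interval net diversification
## rates from fossil and timetree sources, and their correlation.

#' Prune occurrence records to analysis-ready species ranges
#'
#' Species-level records are kept. A genus represented only by
#' species-indeterminate records collapses to a single pseudo-species
#' spanning all of its records; a genus with both determinate and
#' indeterminate records keeps the former and drops the latter. Records
#' with missing ages are skipped (counted in attribute `"nSkipped"`, with a
#' warning).
#'
#' @param records data.frame with columns `genus`, `species` (empty/NA for
#'   indeterminate), `first_ma`, `last_ma`, and optionally `rank`
#'   (`"species"`/`"indet"`; inferred from `species` when absent).
#' @return data.frame with columns `taxon`, `first_ma`, `last_ma`, `rank`;
#'   idempotent under re-application.
#' @export
pruneOccurrences <- function(records) {
  req <- c("genus", "first_ma", "last_ma")
  if (!all(req %in% names(records)))
    stop("records need columns ", paste(req, collapse = ", "))
  if (!"rank" %in% names(records)) {
    sp <- if ("species" %in% names(records)) records$species else
      records$taxon
    records$rank <- ifelse(is.na(sp) | sp == "" |
                             grepl("^(sp\\.?|indet\\.?)$", sp,
                                   ignore.case = TRUE),
                           "indet", "species")
  }
  bad <- is.na(records$first_ma) | is.na(records$last_ma)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped for missing ages")
    records <- records[!bad, , drop = FALSE]
  }
  if (any(records$first_ma < records$last_ma))
    stop("first_ma must be >= last_ma on every record")
  out <- list()
  for (g in unique(records$genus)) {
    gg <- records[records$genus == g, , drop = FALSE]
    det <- gg[gg$rank == "species", , drop = FALSE]
    if (nrow(det)) {
      sp <- if ("species" %in% names(det)) det$species else det$taxon
      for (s in unique(sp)) {
        ss <- det[sp == s, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          taxon = paste(g, s), first_ma = max(ss$first_ma),
          last_ma = min(ss$last_ma), rank = "species",
          stringsAsFactors = FALSE)
      }
    } else {
      out[[length(out) + 1L]] <- data.frame(
        taxon = paste(g, "indet"), first_ma = max(gg$first_ma),
        last_ma = min(gg$last_ma), rank = "indet",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "nSkipped") <- sum(bad)
  res
}

#' Range-through standing diversity at an age
#'
#' Counts taxa whose first-last occurrence interval spans age `t`
#' (boundaries inclusive: a species whose range endpoint equals `t` is
#' counted, matching ranges taken as the complete spanned interval).
#'
#' @param ranges data.frame with columns `first_ma`, `last_ma`.
#' @param t age(s) in Ma.
#' @return integer count(s).
#' @export
standingDiversity <- function(ranges, t) {
  vapply(t, function(ti)
    sum(ranges$first_ma >= ti & ranges$last_ma <= ti), integer(1))
}

#' Standing-diversity curve on an age grid
#'
#' @param ranges as in [standingDiversity()].
#' @param ages sampling grid in Ma (default 1-Myr steps over the Cenozoic).
#' @return data.frame with columns `age`, `count`.
#' @export
diversityCurve <- function(ranges, ages = seq(66, 0, by = -1)) {
  data.frame(age = ages, count = standingDiversity(ranges, ages))
}

#' Per-interval net diversification rate from boundary counts
#'
#' The per-lineage net rate `ln(N_end / N_start) / dt` implied by standing
#' counts at the two interval boundaries (the standard exponential-growth
#' estimator of speciation minus extinction per lineage per Myr); the
#' arithmetic alternative `(N_end - N_start) / (N_start * dt)` is available
#' behind `method`.
#'
#' @param nStart count at the older boundary.
#' @param nEnd count at the younger boundary.
#' @param dt interval length in Myr.
#' @param method `"log"` (default) or `"arithmetic"`.
#' @return the rate; `NA` when either count is zero.
#' @export
intervalRate <- function(nStart, nEnd, dt, method = c("log", "arithmetic")) {
  method <- match.arg(method)
  if (any(dt <= 0)) stop("dt must be positive")
  bad <- nStart <= 0 | nEnd <= 0
  r <- if (method == "log") log(nEnd / nStart) / dt
       else (nEnd - nStart) / (nStart * dt)
  r[bad] <- NA_real_
  r
}

#' Timetree per-interval diversification rates
#'
#' Lineage counts are read off the chronogram's lineage-through-time curve
#' at each boundary and converted to rates with [intervalRate()].
#'
#' @param tree an ultrametric `phylo`.
#' @param boundaries interval boundary ages in Ma, strictly decreasing
#'   (e.g. `seq(55, 0, by = -5)`).
#' @param method passed to [intervalRate()].
#' @return data.frame with columns `start_ma`, `end_ma`, `rate`. An
#'   interval straddling the root uses the single stem lineage at its older
#'   boundary; an interval lying entirely above the root (no tree
#'   information) gets `NA`.
#' @export
timetreeIntervalRates <- function(tree, boundaries, method = "log") {
  if (any(diff(boundaries) >= 0))
    stop("boundaries must be strictly decreasing (old to young)")
  counts <- lineagesAt(tree, boundaries)
  nInt <- length(boundaries) - 1
  root <- max(nodeAges(tree))
  out <- data.frame(start_ma = boundaries[seq_len(nInt)],
                    end_ma = boundaries[seq_len(nInt) + 1],
                    rate = intervalRate(counts[seq_len(nInt)],
                                        counts[seq_len(nInt) + 1],
                                        boundaries[seq_len(nInt)] -
                                          boundaries[seq_len(nInt) + 1],
                                        method = method))
  out$rate[out$end_ma > root] <- NA_real_
  out
}

#' Fossil per-interval diversification rates
#'
#' Range-through standing counts at each boundary, then [intervalRate()].
#'
#' @param ranges as in [standingDiversity()].
#' @param boundaries strictly decreasing boundary ages in Ma.
#' @param method passed to [intervalRate()].
#' @return data.frame as in [timetreeIntervalRates()].
#' @export
fossilIntervalRates <- function(ranges, boundaries, method = "log") {
  if (any(diff(boundaries) >= 0))
    stop("boundaries must be strictly decreasing (old to young)")
  counts <- standingDiversity(ranges, boundaries)
  nInt <- length(boundaries) - 1
  data.frame(start_ma = boundaries[seq_len(nInt)],
             end_ma = boundaries[seq_len(nInt) + 1],
             rate = intervalRate(counts[seq_len(nInt)],
                                 counts[seq_len(nInt) + 1],
                                 boundaries[seq_len(nInt)] -
                                   boundaries[seq_len(nInt) + 1],
                                 method = method))
}

#' Correlate two per-interval rate series
#'
#' Pearson product-moment correlation (the convention behind reported `r`
#' values for fossil-versus-timetree comparisons) with pairwise deletion of
#' missing intervals; Spearman available via `method`.
#'
#' @param a,b numeric rate vectors of equal length (at least 3 complete
#'   pairs after deletion).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient; `NA` with a warning when either
#'   series has zero variance.
#' @export
compareRateSeries <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("series must have equal length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("zero variance in a rate series; correlation undefined")
    return(NA_real_)
  }
  cor(a[ok], b[ok], method = method)
}
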