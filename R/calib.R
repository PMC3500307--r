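## Rule-based construction of minimum/maximum node-age calibration bounds
## (stratigraphic bounding, phylogenetic bracketing) and auditing of a
## chronogram's node ages against a calibration table.

#' Cenozoic chronologic units used for stratigraphic bounding
#'
#' The fourteen units, youngest to oldest, with boundary ages (Ma) after
#' the Gradstein & Ogg geologic time scale: Pleistocene, Pliocene, late
#' Miocene (Tortonian+Messinian), middle Miocene (Langhian+Serravallian),
#' early Miocene (Aquitanian+Burdigalian), late Oligocene (Chattian), early
#' Oligocene (Rupelian), late Eocene (Priabonian), late middle Eocene
#' (Bartonian), early middle Eocene (Lutetian), early Eocene (Ypresian),
#' late Paleocene (Thanetian), middle Paleocene (Selandian), early
#' Paleocene (Danian). The Pleistocene's young boundary is taken to the
#' present. Boundary ages are editable by passing a modified copy to the
#' bounding functions.
#'
#' @return data.frame with columns `unit`, `young_ma`, `old_ma`,
#'   contiguous and strictly increasing in age.
#' @export
chronoUnits <- function() {
  data.frame(
    unit = c("Pleistocene", "Pliocene", "late Miocene", "middle Miocene",
             "early Miocene", "late Oligocene", "early Oligocene",
             "late Eocene", "late middle Eocene", "early middle Eocene",
             "early Eocene", "late Paleocene", "middle Paleocene",
             "early Paleocene"),
    young_ma = c(0, 2.588, 5.332, 11.608, 15.97, 23.03, 28.4, 33.9, 37.2,
                 40.4, 48.6, 55.8, 58.7, 61.7),
    old_ma = c(2.588, 5.332, 11.608, 15.97, 23.03, 28.4, 33.9, 37.2, 40.4,
               48.6, 55.8, 58.7, 61.7, 65.5),
    stringsAsFactors = FALSE)
}

#' Maximum calibration age by stratigraphic bounding
#'
#' Walks rootward from the chronologic unit containing the clade's oldest
#' occurrence until two successive units devoid of the clade's fossils have
#' been traversed; the bound is the old boundary of the second such unit.
#' Units are counted strictly older than the unit holding the oldest
#' occurrence. When fewer than two units remain above it, the old boundary
#' of the oldest unit is returned flagged.
#'
#' @param occurrenceAges ages (Ma) of the clade's occurrences; at least one.
#' @param units a [chronoUnits()]-style table.
#' @return the maximum age in Ma, with logical attribute `"flagged"` set
#'   when the table was exhausted before two empty units were found.
#' @export
stratigraphicMax <- function(occurrenceAges, units = chronoUnits()) {
  if (!length(occurrenceAges) || all(is.na(occurrenceAges)))
    stop("need at least one occurrence age")
  oldest <- max(occurrenceAges, na.rm = TRUE)
  ## unit containing the oldest occurrence: young < age <= old
  i <- which(units$young_ma < oldest & oldest <= units$old_ma)
  if (!length(i)) {
    if (oldest <= units$young_ma[1]) i <- 1L
    else stop("oldest occurrence (", oldest, " Ma) predates the unit table")
  }
  if (i >= nrow(units))
    return(structure(units$old_ma[nrow(units)], flagged = TRUE))
  empty <- 0L
  for (j in seq(i + 1L, nrow(units))) {
    inUnit <- any(occurrenceAges > units$young_ma[j] &
                    occurrenceAges <= units$old_ma[j], na.rm = TRUE)
    if (!inUnit) {
      empty <- empty + 1L
      if (empty == 2L)
        return(structure(units$old_ma[j], flagged = FALSE))
    } else empty <- 0L
  }
  structure(units$old_ma[nrow(units)], flagged = TRUE)
}

#' Maximum calibration age by phylogenetic bracketing
#'
#' The age of the oldest stem fossil attached up to two nodes rootward of
#' the divergence: fossils assigned to the node's parent or grandparent
#' lineages qualify; anything deeper does not.
#'
#' @param tree a `phylo`.
#' @param node ape node number of the divergence being calibrated.
#' @param stemFossils data.frame with columns `node` (ape node number the
#'   fossil attaches to) and `age_ma`.
#' @return the oldest qualifying fossil age, or `NA` when the bracket holds
#'   none.
#' @export
bracketingMax <- function(tree, node, stemFossils) {
  parentOf <- function(v) {
    p <- tree$edge[tree$edge[, 2] == v, 1]
    if (length(p)) p else NA_integer_
  }
  p1 <- parentOf(node)
  if (is.na(p1)) stop("node ", node, " has no ancestor (is it the root?)")
  bracket <- c(p1, parentOf(p1))
  bracket <- bracket[!is.na(bracket)]
  hit <- stemFossils$age_ma[stemFossils$node %in% bracket]
  if (!length(hit)) NA_real_ else max(hit)
}

#' Combine a minimum age with candidate maxima into a calibration bound
#'
#' The maximum is the largest of the contributing maxima (stratigraphic
#' bounding, phylogenetic bracketing, and any user-supplied phylogenetic
#' uncertainty age); it must exceed the minimum.
#'
#' @param minFossil minimum age in Ma (oldest unequivocal crown fossil).
#' @param maxima numeric vector of candidate maxima (NAs dropped; at least
#'   one finite value required).
#' @param clade label used in error messages.
#' @return list of class `calibrationBound`: `clade`, `min_ma`, `max_ma`,
#'   `contributing` (the maxima supplied).
#' @export
combineBounds <- function(minFossil, maxima, clade = "") {
  maxima <- maxima[is.finite(maxima)]
  if (!length(maxima)) stop("no finite maximum supplied for clade ", clade)
  if (minFossil <= 0) stop("minimum age must be positive")
  mx <- max(maxima)
  if (mx <= minFossil)
    stop("inconsistent calibration for clade '", clade, "': max (", mx,
         ") <= min (", minFossil, ")")
  structure(list(clade = clade, min_ma = minFossil, max_ma = mx,
                 contributing = maxima),
            class = "calibrationBound")
}

#' @export
print.calibrationBound <- function(x, ...) {
  cat(sprintf("Calibration %s: min %.2f Ma, max %.2f Ma (from %s)\n",
              x$clade, x$min_ma, x$max_ma,
              paste(format(x$contributing), collapse = ", ")))
  invisible(x)
}

#' Audit chronogram dates against calibration bounds
#'
#' Flags every estimated node age younger than its minimum bound or older
#' than its maximum; the violation magnitude is the (positive) distance to
#' the violated bound, and the mean magnitude is reported over violations
#' only.
#'
#' @param estimates data.frame with columns `clade`, `age_ma` and
#'   optionally `analysis` (an identifier when several chronograms are
#'   audited together).
#' @param bounds data.frame with columns `clade`, `min_ma`, `max_ma`
#'   (either may be NA when only one side is constrained).
#' @return list of class `violationReport`: `violations` (data.frame
#'   `clade`, `analysis`, `bound`, `bound_ma`, `age_ma`, `magnitude_ma`)
#'   and `meanViolation` (NA when there are none).
#' @export
auditViolations <- function(estimates, bounds) {
  if (!all(c("clade", "age_ma") %in% names(estimates)))
    stop("estimates need columns 'clade' and 'age_ma'")
  if (!all(c("clade", "min_ma", "max_ma") %in% names(bounds)))
    stop("bounds need columns 'clade', 'min_ma', 'max_ma'")
  unknown <- setdiff(estimates$clade, bounds$clade)
  if (length(unknown))
    stop("no bounds for clade(s): ", paste(unknown, collapse = ", "))
  if (!"analysis" %in% names(estimates)) estimates$analysis <- ""
  rows <- list()
  for (i in seq_len(nrow(estimates))) {
    b <- bounds[match(estimates$clade[i], bounds$clade), ]
    age <- estimates$age_ma[i]
    if (is.finite(b$min_ma) && age < b$min_ma)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = estimates$clade[i], analysis = estimates$analysis[i],
        bound = "min", bound_ma = b$min_ma, age_ma = age,
        magnitude_ma = b$min_ma - age, stringsAsFactors = FALSE)
    if (is.finite(b$max_ma) && age > b$max_ma)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = estimates$clade[i], analysis = estimates$analysis[i],
        bound = "max", bound_ma = b$max_ma, age_ma = age,
        magnitude_ma = age - b$max_ma, stringsAsFactors = FALSE)
  }
  viol <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clade = character(0), analysis = character(0),
               bound = character(0), bound_ma = numeric(0),
               age_ma = numeric(0), magnitude_ma = numeric(0),
               stringsAsFactors = FALSE)
  structure(list(violations = viol,
                 meanViolation = if (nrow(viol)) mean(viol$magnitude_ma)
                                 else NA_real_),
            class = "violationReport")
}

#' @export
print.violationReport <- function(x, ...) {
  if (!nrow(x$violations)) {
    cat("Calibration audit: no bound violations\n")
  } else {
    cat("Calibration audit:", nrow(x$violations), "violation(s), mean",
        roundHalfUp(x$meanViolation, 1), "Ma\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
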