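# Tumor-response computations: caliper volume, RECIST-style response
# calls, resistance index and Annexin V / propidium iodide quadrant
# classification.

#' Tumor volume from caliper measurements
#'
#' volume = width^2 x length x 0.5, the standard ellipsoid approximation
#' for subcutaneous xenografts.
#'
#' @param width,length caliper dimensions in mm (vectorized; must be > 0).
#' @return volume in mm^3.
#' @examples
#' tumorVolume(10, 10)  # 500
#' @export
tumorVolume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0))
    stop("caliper dimensions must be > 0")
  width^2 * length * 0.5
}

#' RECIST-style response classification from tumor burden
#'
#' Percent change = 100 x (eval - baseline) / baseline. Complete response
#' (CR) when the evaluation burden is 0; partial response (PR) when the
#' change is <= -30; progressive disease (PD) when >= +20; stable disease
#' (SD) otherwise. The published thresholds are defined on diameter sums;
#' \code{mode = "diameter"} cube-root-transforms the volumes into an
#' equivalent diameter before thresholding, \code{mode = "volume"}
#' (default) applies them to the volumes directly.
#'
#' @param baseline,eval tumor volumes (mm^3), vectorized; baseline > 0.
#' @param mode \code{"volume"} or \code{"diameter"}.
#' @return data.frame with \code{percent_change} and \code{category}
#'   (one of \code{"CR"}, \code{"PR"}, \code{"SD"}, \code{"PD"}).
#' @export
recistClassify <- function(baseline, eval, mode = c("volume", "diameter")) {
  mode <- match.arg(mode)
  if (any(baseline <= 0)) stop("baseline volume must be > 0")
  if (any(eval < 0)) stop("evaluation volume must be >= 0")
  b <- baseline; e <- eval
  if (mode == "diameter") { b <- b^(1 / 3); e <- e^(1 / 3) }
  pc <- 100 * (e - b) / b
  category <- ifelse(eval == 0, "CR",
                     ifelse(pc <= -30, "PR",
                            ifelse(pc >= 20, "PD", "SD")))
  data.frame(percent_change = pc, category = category,
             stringsAsFactors = FALSE)
}

#' Resistance index
#'
#' RI = (treated/untreated viability of the resistant line) divided by
#' (treated/untreated viability of the parental line). RI > 1 indicates
#' acquired resistance: the drug hurts the resistant line relatively less.
#'
#' @param treatedResistant,untreatedResistant,treatedParental,untreatedParental
#'   viability means, all > 0.
#' @return the resistance index.
#' @export
resistanceIndex <- function(treatedResistant, untreatedResistant,
                            treatedParental, untreatedParental) {
  v <- c(treatedResistant, untreatedResistant, treatedParental,
         untreatedParental)
  if (any(v <= 0)) stop("all viability means must be > 0")
  (treatedResistant / untreatedResistant) /
    (treatedParental / untreatedParental)
}

#' Annexin V / propidium iodide quadrant classification
#'
#' AV-/PI- intact; AV+/PI- early apoptosis; AV+/PI+ apoptosis; AV-/PI+
#' necrotic/dead (the standard quadrant scheme).
#'
#' @param annexin,pi character vectors of \code{"+"} / \code{"-"} marker
#'   states.
#' @return character vector: \code{"intact"}, \code{"early_apoptosis"},
#'   \code{"apoptosis"} or \code{"necrotic_dead"}.
#' @export
classifyFlowEvent <- function(annexin, pi) {
  if (!all(annexin %in% c("+", "-")) || !all(pi %in% c("+", "-")))
    stop("marker states must be '+' or '-'")
  ifelse(annexin == "-" & pi == "-", "intact",
         ifelse(annexin == "+" & pi == "-", "early_apoptosis",
                ifelse(annexin == "+" & pi == "+", "apoptosis",
                       "necrotic_dead")))
}

#' Per-animal RECIST calls along a growth-curve set
#'
#' Computes caliper volumes (after swap-normalizing width <= length) and
#' classifies each post-baseline day. As in the standard response
#' criteria, response (CR/PR) is judged against the baseline burden while
#' progression (PD) is judged against the nadir -- the smallest burden
#' observed so far -- so a tumor regrowing after deep shrinkage is called
#' progressive as soon as it rises 20\% above its minimum, not only once
#' it re-passes baseline.
#'
#' @param curves growth-curve data.frame (columns \code{animal},
#'   \code{arm}, \code{day}, \code{width_mm}, \code{length_mm}), e.g. from
#'   \code{\link{simulateGrowthCurves}}.
#' @param baselineDay day used as baseline (default: each animal's first
#'   day).
#' @param mode passed to \code{\link{recistClassify}}.
#' @return data.frame with columns \code{animal}, \code{arm},
#'   \code{baseline_day}, \code{day}, \code{volume_mm3},
#'   \code{percent_change} (vs baseline), \code{percent_change_nadir},
#'   \code{category}.
#' @export
responseCalls <- function(curves, baselineDay = NULL,
                          mode = c("volume", "diameter")) {
  mode <- match.arg(mode)
  w <- pmin(curves$width_mm, curves$length_mm)
  l <- pmax(curves$width_mm, curves$length_mm)
  curves$volume_mm3 <- tumorVolume(w, l)
  out <- lapply(split(curves, curves$animal), function(a) {
    a <- a[order(a$day), , drop = FALSE]
    b0 <- if (is.null(baselineDay)) a$day[1] else baselineDay
    base <- a$volume_mm3[a$day == b0]
    if (length(base) != 1)
      stop("animal ", a$animal[1], ": no unique measurement at baseline ",
           "day ", b0)
    ev <- a[a$day > b0, , drop = FALSE]
    nadir <- cummin(c(base, ev$volume_mm3))[seq_len(nrow(ev))]
    vsBase <- recistClassify(base, ev$volume_mm3, mode)
    vsNadir <- recistClassify(nadir, ev$volume_mm3, mode)
    category <- ifelse(ev$volume_mm3 == 0, "CR",
                       ifelse(vsNadir$category == "PD", "PD",
                              ifelse(vsBase$category == "PR", "PR", "SD")))
    data.frame(animal = ev$animal, arm = ev$arm, baseline_day = b0,
               day = ev$day, volume_mm3 = ev$volume_mm3,
               percent_change = vsBase$percent_change,
               percent_change_nadir = vsNadir$percent_change,
               category = category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
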