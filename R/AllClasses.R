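#' @import methods
NULL

.WELL_TYPES <- c("compound", "pos_ctrl", "neg_ctrl", "empty")

#' PlateData: all wells of one physical screening plate
#'
#' Container for one plate of a multi-dose drug screen. Wells live in a
#' long-format \code{data.frame} with one row per well and columns
#' \code{row}, \code{col} (1-based integers; row 1 = "A", col 1 = leftmost),
#' \code{wellType} (one of \code{"compound"}, \code{"pos_ctrl"},
#' \code{"neg_ctrl"}, \code{"empty"}), \code{compoundId} (character,
#' \code{NA} for non-compound wells), \code{concentration} (micromolar,
#' \code{NA} for non-compound wells) and \code{response} (percent
#' inhibition; negative control approximately 0, positive control
#' approximately 100; values are deliberately not clipped to [0, 100] --
#' overshoots carry artifact information).
#'
#' @slot plateId character(1), opaque plate identifier.
#' @slot nRows,nCols integer(1), plate geometry (96-well: 8 x 12;
#'   384-well: 16 x 24).
#' @slot wells data.frame as described above.
#' @slot metadata free-form named list.
#'
#' @seealso [PlateData()] for the user-facing constructor,
#'   [extractDoseSeries()], [plateQC()].
#' @export
setClass("PlateData",
  slots = c(
    plateId = "character",
    nRows = "integer",
    nCols = "integer",
    wells = "data.frame",
    metadata = "list"
  )
)

setValidity("PlateData", function(object) {
  msgs <- character()
  w <- object@wells
  need <- c("row", "col", "wellType", "compoundId", "concentration", "response")
  if (!all(need %in% names(w))) {
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  }
  if (length(object@plateId) != 1L || is.na(object@plateId)) {
    msgs <- c(msgs, "plateId must be a single non-NA string")
  }
  if (object@nRows < 1L || object@nCols < 1L) {
    msgs <- c(msgs, "plate geometry must be positive")
  }
  if (nrow(w) > 0L) {
    if (!all(w$wellType %in% .WELL_TYPES)) {
      msgs <- c(msgs, paste("wellType must be one of:", paste(.WELL_TYPES, collapse = ", ")))
    }
    if (any(w$row < 1L) || any(w$row > object@nRows) ||
        any(w$col < 1L) || any(w$col > object@nCols)) {
      msgs <- c(msgs, "well coordinates outside plate geometry")
    }
    if (anyDuplicated(w[, c("row", "col")])) {
      msgs <- c(msgs, "duplicated (row, col) well positions")
    }
    cmp <- w$wellType == "compound"
    if (any(cmp & (is.na(w$compoundId) | is.na(w$concentration)))) {
      msgs <- c(msgs, "compound wells must carry compoundId and concentration")
    }
    if (any(cmp & !is.na(w$concentration) & w$concentration <= 0)) {
      msgs <- c(msgs, "compound concentrations must be > 0 (micromolar)")
    }
    if (any(!cmp & (!is.na(w$compoundId) | !is.na(w$concentration)))) {
      msgs <- c(msgs, "control/empty wells must not carry compoundId or concentration")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DoseSeries: one compound's dose-response measurements on a plate
#'
#' Ordered measurements for a single compound, sorted by ascending
#' concentration. Replicates at the same concentration are kept as separate
#' points: each replicate contributes independently to curve fitting and
#' residual computation. Well coordinates are retained for spatial
#' drill-down.
#'
#' @slot compoundId character(1).
#' @slot points data.frame with columns \code{concentration} (micromolar,
#'   > 0), \code{response} (percent inhibition), \code{row}, \code{col}.
#' @export
setClass("DoseSeries",
  slots = c(compoundId = "character", points = "data.frame")
)

setValidity("DoseSeries", function(object) {
  p <- object@points
  need <- c("concentration", "response", "row", "col")
  if (!all(need %in% names(p))) {
    return(paste("points must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(p) < 1L) return("a dose series needs at least one point")
  if (any(p$concentration <= 0)) return("concentrations must be > 0")
  if (is.unsorted(p$concentration)) return("points must be sorted by ascending concentration")
  TRUE
})

#' ControlSummary: location/scale of a plate's control wells
#'
#' Mean and sample (n-1) standard deviation, plus median and
#' normal-consistent MAD (scale constant 1.4826), of the positive and
#' negative control responses of one plate. Depends only on control
#' response values, never on control positions.
#'
#' @slot muP,sigmaP,muN,sigmaN mean / sd of positive and negative controls
#'   (percent inhibition).
#' @slot medP,madP,medN,madN robust analogues.
#' @slot nPos,nNeg control well counts (each >= 2).
#' @export
setClass("ControlSummary",
  slots = c(
    muP = "numeric", sigmaP = "numeric", muN = "numeric", sigmaN = "numeric",
    medP = "numeric", madP = "numeric", medN = "numeric", madN = "numeric",
    nPos = "integer", nNeg = "integer"
  )
)

setValidity("ControlSummary", function(object) {
  if (object@nPos < 2L || object@nNeg < 2L) {
    return("control summaries need >= 2 wells of each control type")
  }
  if (any(c(object@sigmaP, object@sigmaN, object@madP, object@madN) < 0)) {
    return("scale estimates must be non-negative")
  }
  TRUE
})

.FIT_STATUS <- c("converged", "fallback_flat", "fallback_constrained", "failed")

#' LL4Fit: a four-parameter log-logistic fit for one dose series
#'
#' The model is f(x) = d + (a - d) / (1 + (x / c)^b) with a the minimum
#' (low-dose) asymptote, d the maximum asymptote, b > 0 the slope (so
#' inhibition increases with dose) and c the inflection point (IC50,
#' micromolar). Residuals are absolute deviations |y - f(x)| per individual
#' replicate measurement.
#'
#' @slot a,b,c,d fitted parameters (see above); for the flat fallback
#'   a = d = mean response and b, c are NA.
#' @slot fitted numeric, f(x) at each series point (percent inhibition).
#' @slot residuals numeric, |y - f(x)| per point (>= 0).
#' @slot status one of "converged", "fallback_flat",
#'   "fallback_constrained", "failed".
#' @slot lowConfidence logical(1), TRUE when the series has 3 or fewer
#'   distinct concentrations.
#' @export
setClass("LL4Fit",
  slots = c(
    a = "numeric", b = "numeric", c = "numeric", d = "numeric",
    fitted = "numeric", residuals = "numeric",
    status = "character", lowConfidence = "logical"
  )
)

setValidity("LL4Fit", function(object) {
  if (!object@status %in% .FIT_STATUS) {
    return(paste("status must be one of:", paste(.FIT_STATUS, collapse = ", ")))
  }
  if (length(object@fitted) != length(object@residuals)) {
    return("fitted and residuals must have equal length")
  }
  if (any(object@residuals < 0, na.rm = TRUE)) return("residuals must be >= 0")
  if (object@status == "converged" && (!is.finite(object@c) || object@c <= 0)) {
    return("converged fits must have c > 0")
  }
  TRUE
})

.TIERS <- c("acceptable", "borderline", "poor")

#' PlateQCResult: all quality metrics for one plate
#'
#' @slot plateId character(1).
#' @slot nrfe plate-level Normalized Residual Fit Error (>= 0).
#' @slot tier "acceptable" (NRFE < 10), "borderline" (10 <= NRFE <= 15) or
#'   "poor" (NRFE > 15) under the default thresholds.
#' @slot controlMetrics named list with z_prime, robust_z_prime, ssmd, s_b
#'   (each numeric, possibly an undefined marker: NA with a "reason"
#'   attribute), or an empty list when controls are insufficient.
#' @slot nSeriesUsed,nSeriesExcluded counts of dose series entering /
#'   excluded from the NRFE mean.
#' @slot perSeriesNRFE named numeric, per-compound mean scaled residual.
#' @export
setClass("PlateQCResult",
  slots = c(
    plateId = "character",
    nrfe = "numeric",
    tier = "character",
    controlMetrics = "list",
    nSeriesUsed = "integer",
    nSeriesExcluded = "integer",
    perSeriesNRFE = "numeric"
  )
)

setValidity("PlateQCResult", function(object) {
  if (!object@tier %in% .TIERS) {
    return(paste("tier must be one of:", paste(.TIERS, collapse = ", ")))
  }
  if (is.finite(object@nrfe) && object@nrfe < 0) return("nrfe must be >= 0")
  if (object@nSeriesUsed < 1L) return("at least one series must enter NRFE")
  TRUE
})

#' @describeIn PlateData-class compact display
#' @param object a PlateData
#' @export
setMethod("show", "PlateData", function(object) {
  w <- object@wells
  cat(sprintf(
    "PlateData '%s' (%d x %d)\n  %d wells: %d compound, %d pos_ctrl, %d neg_ctrl, %d empty\n  %d dose series\n",
    object@plateId, object@nRows, object@nCols, nrow(w),
    sum(w$wellType == "compound"), sum(w$wellType == "pos_ctrl"),
    sum(w$wellType == "neg_ctrl"), sum(w$wellType == "empty"),
    length(unique(w$compoundId[w$wellType == "compound"]))
  ))
})

#' @describeIn LL4Fit-class compact display
#' @param object an LL4Fit
#' @export
setMethod("show", "LL4Fit", function(object) {
  cat(sprintf(
    "LL4Fit [%s]%s a=%.3g d=%.3g b=%.3g c=%.3g uM; %d points, mean |resid| = %.3g\n",
    object@status, if (object@lowConfidence) " (low confidence)" else "",
    object@a, object@d, object@b, object@c,
    length(object@residuals), mean(object@residuals)
  ))
})

#' @describeIn PlateQCResult-class compact display
#' @param object a PlateQCResult
#' @export
setMethod("show", "PlateQCResult", function(object) {
  cm <- object@controlMetrics
  fmt <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.3g", x)
  cat(sprintf(
    "PlateQCResult '%s': NRFE = %.3g [%s]\n  series used: %d, excluded: %d\n  Z' = %s, robust Z' = %s, SSMD = %s, S/B = %s\n",
    object@plateId, object@nrfe, object@tier,
    object@nSeriesUsed, object@nSeriesExcluded,
    fmt(cm$z_prime), fmt(cm$robust_z_prime), fmt(cm$ssmd), fmt(cm$s_b)
  ))
})
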