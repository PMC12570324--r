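#' Binomial scaling factor for dose-response residuals
#'
#' k = 1 + p(1 - p) / 0.25, where p is the fitted response proportion
#' (fitted percent inhibition / 100), clamped to [0, 1] before use so
#' that overshooting fits cannot push k below 1. The factor is symmetric
#' about p = 0.5, where it attains its maximum of 2, and equals 1 at the
#' asymptotes (p = 0 or 1): residuals in the steep, information-rich part
#' of the curve are up-weighted, mirroring the binomial variance
#' structure of proportion-scale responses.
#'
#' @param p fitted response proportion(s); any real value, clamped
#'   internally.
#' @return scaling factor(s) in [1, 2].
#' @examples
#' scalingFactor(c(0, 0.5, 1, 1.2))  # 1, 2, 1, 1
#' @export
scalingFactor <- function(p) {
  p <- .clamp(p, 0, 1)
  1 + p * (1 - p) / 0.25
}

#' Per-series mean scaled residual
#'
#' (1 / n_i) * sum_j |eps_ij * k_ij| over the n_i individual replicate
#' measurements of series i, where eps_ij = |y_ij - f(x_ij)| and k_ij is
#' the [scalingFactor()] at the fitted response proportion f(x_ij) / 100.
#'
#' @param fit an [LL4Fit-class] with populated fitted values and
#'   residuals.
#' @return a single non-negative number.
#' @export
seriesNRFE <- function(fit) {
  stopifnot(is(fit, "LL4Fit"))
  k <- scalingFactor(fit@fitted / 100)
  mean(abs(fit@residuals * k))
}

#' Plate-level Normalized Residual Fit Error
#'
#' NRFE = (1 / N) * sum_i (1 / n_i) * sum_j |eps_ij * k_ij|: the
#' unweighted mean over the plate's N fitted dose series of each series'
#' mean scaled residual ([seriesNRFE()]). Residuals are computed per
#' individual replicate measurement, never from averaged responses.
#' Because NRFE uses only compound wells and their fitted curves, it is
#' independent of control wells and of well positions, and so detects
#' spatial artifacts in the drug-treated area that control-based metrics
#' are blind to.
#'
#' @param plate a [PlateData-class].
#' @param fits named list of [LL4Fit-class], one per dose series of the
#'   plate (as produced by [fitLL4()] over [extractDoseSeries()]). Fits
#'   with status \code{"failed"} are excluded from the mean and counted.
#' @param weighting \code{"series"} (default): every dose series weighs
#'   equally in the outer mean. \code{"wells"}: series are weighted by
#'   their number of measurements n_i, i.e. every compound well weighs
#'   equally.
#' @param thresholds length-2 numeric c(borderline, poor) passed to
#'   [classifyTier()].
#' @param controls optional [ControlSummary-class]; when supplied the
#'   result also carries the control-based metrics. Use [plateQC()] for
#'   the full pipeline.
#' @return a [PlateQCResult-class].
#' @export
plateNRFE <- function(plate, fits, weighting = c("series", "wells"),
                      thresholds = c(10, 15), controls = NULL) {
  stopifnot(is(plate, "PlateData"))
  weighting <- match.arg(weighting)
  ok <- vapply(fits, function(f) fitStatus(f) != "failed", TRUE)
  nExcluded <- sum(!ok)
  fits <- fits[ok]
  if (length(fits) == 0L) {
    .htsqcError(
      sprintf(
        "plate '%s': no fittable dose series (all %d excluded); NRFE unavailable",
        plateId(plate), nExcluded
      ),
      "noNRFEError"
    )
  }
  perSeries <- vapply(fits, seriesNRFE, 0)
  value <- if (weighting == "series") {
    mean(perSeries)
  } else {
    ni <- vapply(fits, function(f) length(fitResiduals(f)), 0L)
    sum(perSeries * ni) / sum(ni)
  }
  cm <- if (is.null(controls)) list() else controlMetrics(controls)
  new("PlateQCResult",
    plateId = plateId(plate),
    nrfe = value,
    tier = classifyTier(value, thresholds),
    controlMetrics = cm,
    nSeriesUsed = length(fits),
    nSeriesExcluded = as.integer(nExcluded),
    perSeriesNRFE = perSeries
  )
}

#' Classify a plate NRFE value into a quality tier
#'
#' Default cutoffs: NRFE < 10 acceptable; 10 to 15 (inclusive on both
#' boundaries) borderline, needing scrutiny; > 15 poor, requiring review
#' or exclusion.
#'
#' @param nrfe a non-negative NRFE value.
#' @param thresholds c(borderline, poor) cutoffs; values at the cutoffs
#'   fall into the borderline tier.
#' @return "acceptable", "borderline" or "poor".
#' @export
classifyTier <- function(nrfe, thresholds = c(10, 15)) {
  stopifnot(length(nrfe) == 1L, is.finite(nrfe))
  if (nrfe < 0) .htsqcError("NRFE must be non-negative", "contractViolation")
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  if (nrfe < thresholds[1]) "acceptable"
  else if (nrfe <= thresholds[2]) "borderline"
  else "poor"
}

#' Full per-plate QC pipeline
#'
#' Extracts dose series, fits the LL4 model to each, and assembles the
#' plate's NRFE, tier and control-based metrics into one
#' [PlateQCResult-class]. Unfittable series (fewer than 2 distinct
#' concentrations) are excluded and counted; insufficient controls leave
#' the control metrics absent without affecting NRFE.
#'
#' @param plate a [PlateData-class].
#' @param thresholds,weighting passed to [plateNRFE()].
#' @param outlierHandling passed to [fitLL4()].
#' @param returnFits if TRUE, attach the per-series fits as attribute
#'   \code{"fits"} on the result.
#' @return a [PlateQCResult-class].
#' @examples
#' sim <- simulatePlate(plateSimConfig(seed = 1))
#' plateQC(sim$plate)
#' @export
plateQC <- function(plate, thresholds = c(10, 15),
                    weighting = c("series", "wells"),
                    outlierHandling = FALSE, returnFits = FALSE) {
  series <- extractDoseSeries(plate)
  fits <- list()
  nUnfittable <- 0L
  for (id in names(series)) {
    f <- tryCatch(
      fitLL4(series[[id]], outlierHandling = outlierHandling),
      unfittableSeriesError = function(e) NULL
    )
    if (is.null(f)) nUnfittable <- nUnfittable + 1L else fits[[id]] <- f
  }
  if (length(fits) == 0L) {
    .htsqcError(
      sprintf("plate '%s': all %d series unfittable", plateId(plate), nUnfittable),
      "noNRFEError"
    )
  }
  controls <- tryCatch(summarizeControls(plate),
    insufficientControlsError = function(e) NULL
  )
  res <- plateNRFE(plate, fits,
    weighting = weighting, thresholds = thresholds, controls = controls
  )
  res@nSeriesExcluded <- res@nSeriesExcluded + nUnfittable
  if (returnFits) attr(res, "fits") <- fits
  res
}
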