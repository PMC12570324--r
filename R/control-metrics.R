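#' Control-based plate quality metrics
#'
#' The four traditional control-well metrics of HTS plate QC, computed on
#' the percent-inhibition scale from a [ControlSummary-class]:
#' \describe{
#'   \item{Z-prime}{\eqn{Z' = 1 - 3(\sigma_p + \sigma_n) / |\mu_p - \mu_n|};
#'     at most 1, conventionally acceptable above 0.5.}
#'   \item{robust Z-prime}{the same with medians and normal-consistent MADs
#'     substituted for means and standard deviations.}
#'   \item{SSMD}{\eqn{(\mu_p - \mu_n) / \sqrt{\sigma_p^2 + \sigma_n^2}}.}
#'   \item{S/B}{\eqn{\mu_p / \mu_n}, the signal-to-background ratio.
#'     Computed on the stored response scale; on the inhibition scale
#'     negative controls center on 0, so S/B is frequently undefined --
#'     this is a documented caveat of that metric, not of the plate.}
#' }
#' Degenerate inputs (zero denominators) yield an undefined-metric marker
#' (see [undefinedMetric()]) rather than an error, so a broken control
#' metric never blocks NRFE computation.
#'
#' @param cs a [ControlSummary-class].
#' @return a single numeric, or an NA undefined marker with a reason.
#' @seealso [controlMetrics()] for all four at once; [plateQC()].
#' @examples
#' cs <- ControlSummary(muP = 100, sigmaP = 5, muN = 0, sigmaN = 5)
#' zPrime(cs)  # 0.7
#' ssmd(cs)    # 14.14
#' @name control-metrics
NULL

#' @rdname control-metrics
#' @export
zPrime <- function(cs) {
  stopifnot(is(cs, "ControlSummary"))
  den <- abs(cs@muP - cs@muN)
  if (den == 0) {
    return(undefinedMetric("positive and negative control means are equal"))
  }
  1 - 3 * (cs@sigmaP + cs@sigmaN) / den
}

#' @rdname control-metrics
#' @export
robustZPrime <- function(cs) {
  stopifnot(is(cs, "ControlSummary"))
  den <- abs(cs@medP - cs@medN)
  if (den == 0) {
    return(undefinedMetric("positive and negative control medians are equal"))
  }
  1 - 3 * (cs@madP + cs@madN) / den
}

#' @rdname control-metrics
#' @export
ssmd <- function(cs) {
  stopifnot(is(cs, "ControlSummary"))
  den <- sqrt(cs@sigmaP^2 + cs@sigmaN^2)
  if (den == 0) {
    return(undefinedMetric("both control standard deviations are zero"))
  }
  (cs@muP - cs@muN) / den
}

#' @rdname control-metrics
#' @export
signalToBackground <- function(cs) {
  stopifnot(is(cs, "ControlSummary"))
  if (cs@muN == 0) {
    return(undefinedMetric("negative control mean is zero"))
  }
  cs@muP / cs@muN
}

#' @describeIn control-metrics all four metrics as a named list
#'   (z_prime, robust_z_prime, ssmd, s_b).
#' @param object a [ControlSummary-class].
#' @param ... unused.
#' @export
setMethod("controlMetrics", "ControlSummary", function(object, ...) {
  list(
    z_prime = zPrime(object),
    robust_z_prime = robustZPrime(object),
    ssmd = ssmd(object),
    s_b = signalToBackground(object)
  )
})

#' @describeIn control-metrics retrieve the metrics stored on a QC result.
#' @export
setMethod("controlMetrics", "PlateQCResult", function(object, ...) {
  object@controlMetrics
})
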