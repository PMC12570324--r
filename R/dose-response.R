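#' Four-parameter log-logistic dose-response model
#'
#' \code{ll4} evaluates f(x) = d + (a - d) / (1 + (x / c)^b) at
#' concentrations \code{x} (micromolar). With b > 0 the response rises
#' from the low-dose asymptote a towards the high-dose asymptote d as the
#' dose increases; c is the inflection point (IC50).
#'
#' @param x concentrations (micromolar, > 0).
#' @param a,b,c,d model parameters.
#' @return fitted percent inhibition at each x.
#' @export
ll4 <- function(x, a, b, c, d) {
  d + (a - d) / (1 + (x / c)^b)
}

## Default optimisation box. Slope sign-fixed positive so inhibition
## increases with dose; asymptote boxes tolerate moderate overshoot of the
## nominal 0-100 scale; c is confined to two decades around the tested
## range (set per series).
.LL4_BOUNDS <- list(a = c(-20, 60), d = c(40, 120), b = c(0.2, 10))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Residual vector for the LM optimizer, parametrized in
## (a, d, log10 b, log10 c) and evaluated in log10-dose space for
## numerical stability.
.ll4Resid <- function(par, lx, y, w) {
  eta <- 10^par[["lb10"]] * (lx - par[["lc10"]]) * log(10)
  eta <- .clamp(eta, -700, 700)
  f <- par[["d"]] + (par[["a"]] - par[["d"]]) / (1 + exp(eta))
  sqrt(w) * (y - f)
}

.flatFit <- function(y, lowConf, status = "fallback_flat") {
  m <- mean(y)
  new("LL4Fit",
    a = m, b = NA_real_, c = NA_real_, d = m,
    fitted = rep(m, length(y)), residuals = abs(y - m),
    status = status, lowConfidence = lowConf
  )
}

#' Fit the four-parameter log-logistic model to a dose series
#'
#' Bounded least squares (Levenberg-Marquardt, via \pkg{minpack.lm}) on
#' (a, d, log10 b, log10 c) in log10-concentration space. Replicate points
#' carry equal weight: each replicate measurement contributes its own
#' residual. Initialisation is deterministic (a = min response, d = max
#' response, b = 1, c = the tested concentration nearest the half-range
#' crossing), so fits are reproducible without random restarts.
#'
#' Bounds: a in [-20, 60], d in [40, 120], b in [0.2, 10] (sign-fixed so
#' inhibition increases with dose), c within [min dose / 100, max dose x
#' 100]. Deterministic fallbacks keep every fittable series usable:
#' \itemize{
#'   \item optimizer failure, or a response span below 10 percentage
#'     points (inactive or uniformly potent compounds): flat model
#'     f(x) = mean(y), status \code{"fallback_flat"};
#'   \item a converged c pinned to the edge of its box: re-fit with c
#'     held at the boundary, status \code{"fallback_constrained"}.
#' }
#' Fitted values and residuals |y - f(x)| are always populated.
#'
#' @param series a [DoseSeries-class] with at least 2 distinct
#'   concentrations (an unfittable series raises an error; callers such as
#'   [plateQC()] catch it and count the exclusion). Series with 3 or fewer
#'   distinct concentrations are flagged low-confidence.
#' @param outlierHandling if TRUE, one IQR-based down-weighting pass: the
#'   single worst point, when its residual exceeds Q3 + 1.5 IQR of the
#'   residual distribution, is down-weighted to 0.25 and the model re-fit.
#'   Off by default so that residuals reflect raw artifacts.
#' @return an [LL4Fit-class].
#' @examples
#' s <- new("DoseSeries", compoundId = "drugA", points = data.frame(
#'   concentration = 10^seq(-3, 1, 0.5),
#'   response = ll4(10^seq(-3, 1, 0.5), a = 0, b = 1, c = 0.1, d = 90),
#'   row = 1L, col = 1:9
#' ))
#' fitLL4(s)
#' @export
fitLL4 <- function(series, outlierHandling = FALSE) {
  stopifnot(is(series, "DoseSeries"))
  p <- seriesPoints(series)
  x <- p$concentration
  y <- p$response
  nDistinct <- length(unique(x))
  if (nDistinct < 2L) {
    .htsqcError(
      sprintf(
        "series '%s' has %d distinct concentration(s); >= 2 required for fitting",
        compoundId(series), nDistinct
      ),
      "unfittableSeriesError"
    )
  }
  lowConf <- nDistinct <= 3L
  if (diff(range(y)) < 10) {
    return(.flatFit(y, lowConf))
  }
  fit <- .fitLL4Core(x, y, rep(1, length(y)), lowConf)
  if (outlierHandling && fit@status != "fallback_flat") {
    r <- fit@residuals
    cut <- stats::quantile(r, 0.75) + 1.5 * stats::IQR(r)
    worst <- which.max(r)
    if (r[worst] > cut) {
      w <- rep(1, length(y))
      w[worst] <- 0.25
      refit <- .fitLL4Core(x, y, w, lowConf)
      if (refit@status != "fallback_flat") fit <- refit
    }
  }
  fit
}

## Bounded LM on the free-parameter subset; fixed parameters are merged
## back into the full vector. Returns the full named parameter vector or
## NULL on optimizer failure.
.runLM <- function(start, free, lx, y, w, lower, upper) {
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
  fixed <- start[setdiff(names(start), free)]
  sol <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start[free],
      fn = function(q, lx, y, w) .ll4Resid(c(q, fixed), lx, y, w),
      lx = lx, y = y, w = w,
      lower = lower[free], upper = upper[free], control = ctl
    )),
    error = function(e) NULL
  )
  if (is.null(sol) || !all(is.finite(unlist(sol$par)))) return(NULL)
  out <- c(unlist(sol$par), fixed)
  out[names(start)]
}

.fitLL4Core <- function(x, y, w, lowConf) {
  lx <- log10(x)
  nd <- length(unique(x))
  cBox <- c(min(x) / 100, max(x) * 100)
  b0 <- .LL4_BOUNDS
  half <- (min(y) + max(y)) / 2
  start <- c(
    a = .clamp(min(y), b0$a[1], b0$a[2]),
    d = .clamp(max(y), b0$d[1], b0$d[2]),
    lb10 = 0,
    lc10 = lx[which.min(abs(y - half))]
  )
  lower <- c(a = b0$a[1], d = b0$d[1], lb10 = log10(b0$b[1]), lc10 = log10(cBox[1]))
  upper <- c(a = b0$a[2], d = b0$d[2], lb10 = log10(b0$b[2]), lc10 = log10(cBox[2]))
  ## never more free parameters than distinct concentrations: with 3
  ## distinct doses the slope is held at 1, with 2 the lower asymptote is
  ## additionally pinned at the observed minimum
  free <- if (nd >= 4L) c("a", "d", "lb10", "lc10")
          else if (nd == 3L) c("a", "d", "lc10")
          else c("d", "lc10")
  par <- .runLM(start, free, lx, y, w, lower, upper)
  if (is.null(par)) {
    return(.flatFit(y, lowConf))
  }
  status <- "converged"
  tol <- 1e-8
  ## c pinned to the edge of its box: hold it there and re-fit the rest
  if (par[["lc10"]] <= lower[["lc10"]] + tol || par[["lc10"]] >= upper[["lc10"]] - tol) {
    par[["lc10"]] <- .clamp(par[["lc10"]], lower[["lc10"]], upper[["lc10"]])
    par2 <- .runLM(par, setdiff(free, "lc10"), lx, y, w, lower, upper)
    if (!is.null(par2)) par <- par2
    status <- "fallback_constrained"
  }
  a <- par[["a"]]; d <- par[["d"]]
  b <- 10^par[["lb10"]]; cc <- 10^par[["lc10"]]
  f <- ll4(x, a, b, cc, d)
  new("LL4Fit",
    a = a, b = b, c = cc, d = d,
    fitted = f, residuals = abs(y - f),
    status = status, lowConfidence = lowConf
  )
}

#' Dose-response summary metrics from a fitted curve
#'
#' Computes the three standard sensitivity summaries over the tested
#' log10-concentration interval:
#' \describe{
#'   \item{ic50}{the fitted inflection point c (micromolar). Marked
#'     not-reached (\code{ic50Reached = FALSE}) when the fitted curve does
#'     not cross 50 percent inhibition within the tested range, including
#'     all flat fallbacks.}
#'   \item{auc}{mean fitted inhibition over the tested log10 range, with
#'     the integrand clamped to [0, 100]; 0-100 scale.}
#'   \item{dss}{drug sensitivity score: area between the fitted curve and
#'     a 10 percent inhibition activity floor, normalised by the maximal
#'     possible area above the floor over the tested range, times 100.
#'     Curves never exceeding the floor score 0.}
#' }
#'
#' @param fit an [LL4Fit-class] (status \code{"failed"} yields undefined
#'   markers for every metric).
#' @param series the [DoseSeries-class] the fit came from (supplies the
#'   tested concentration range).
#' @param dssFloor activity floor for DSS, percent inhibition (default 10).
#' @param nGrid trapezoid grid size for the curve integrals.
#' @return named list: \code{ic50}, \code{ic50Reached}, \code{auc},
#'   \code{dss}.
#' @export
computeResponseMetrics <- function(fit, series, dssFloor = 10, nGrid = 201L) {
  stopifnot(is(fit, "LL4Fit"), is(series, "DoseSeries"))
  if (fit@status == "failed") {
    return(list(
      ic50 = undefinedMetric("fit failed"), ic50Reached = FALSE,
      auc = undefinedMetric("fit failed"), dss = undefinedMetric("fit failed")
    ))
  }
  x <- seriesPoints(series)$concentration
  lrange <- range(log10(x))
  lg <- seq(lrange[1], lrange[2], length.out = nGrid)
  f <- if (fit@status == "fallback_flat" || !is.finite(fit@b)) {
    rep(fit@a, nGrid)
  } else {
    ll4(10^lg, fit@a, fit@b, fit@c, fit@d)
  }
  fcl <- .clamp(f, 0, 100)
  width <- diff(lrange)
  trap <- function(v) {
    if (width == 0) return(mean(v))
    sum((v[-1] + v[-nGrid]) / 2 * diff(lg)) / width
  }
  auc <- trap(fcl)
  dss <- if (all(fcl <= dssFloor)) 0 else trap(pmax(fcl - dssFloor, 0)) / (100 - dssFloor) * 100
  reached <- FALSE
  if (fit@status != "fallback_flat" && is.finite(fit@b)) {
    fEnds <- ll4(range(x), fit@a, fit@b, fit@c, fit@d)
    reached <- (fEnds[1] - 50) * (fEnds[2] - 50) <= 0
  }
  list(ic50 = fit@c, ic50Reached = reached, auc = auc, dss = dss)
}
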