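## Shared internal helpers: conditions, undefined-metric markers, local RNG.

.htsqcError <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "htsqcError"), call = call))
}

#' Undefined-metric markers
#'
#' A QC metric that cannot be computed (e.g. Z-prime with identical control
#' means) is reported as \code{NA} carrying a \code{"reason"} attribute
#' rather than as an error, so that one broken control metric never blocks
#' the control-independent NRFE.
#'
#' @param reason character(1) explaining why the metric is undefined.
#' @return \code{undefinedMetric}: NA with a reason attribute.
#' @export
undefinedMetric <- function(reason) {
  structure(NA_real_, reason = reason)
}

#' @rdname undefinedMetric
#' @param x a metric value.
#' @return \code{metricReason}: the reason string, or NULL for a defined
#'   metric.
#' @export
metricReason <- function(x) attr(x, "reason", exact = TRUE)

#' @rdname undefinedMetric
#' @return \code{isUndefinedMetric}: TRUE when the metric carries an
#'   undefined marker.
#' @export
isUndefinedMetric <- function(x) is.na(x) && !is.null(metricReason(x))

## Run `expr` under a fixed seed without disturbing the caller's RNG
## stream. All simulator randomness flows through this, so outputs are pure
## functions of (config, seed).
withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a distinct 31-bit sub-seed from a base seed and a stream index.
subSeed <- function(seed, k) {
  ## double arithmetic: products stay exact below 2^53, well above the
  ## 1103 * 2^31 worst case here
  as.integer((as.numeric(seed) * 1103 + as.numeric(k) * 12289) %% 2147483563)
}

#' Convert between well labels and 1-based coordinates
#'
#' "A01" (or "A1") maps to row 1, col 1; rows beyond "Z" use the common
#' "AA", "AB", ... extension.
#'
#' @param label character vector of well labels.
#' @return \code{wellLabelToCoords}: data.frame with integer columns
#'   \code{row}, \code{col}.
#' @export
wellLabelToCoords <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    .htsqcError(
      sprintf("malformed well label(s): %s", paste(label[bad], collapse = ", ")),
      "wellLabelError"
    )
  }
  letters_part <- toupper(vapply(m, `[`, "", 2L))
  row <- vapply(strsplit(letters_part, ""), function(ch) {
    sum((match(ch, LETTERS)) * 26L^(rev(seq_along(ch)) - 1L))
  }, 1)
  col <- as.integer(vapply(m, `[`, "", 3L))
  data.frame(row = as.integer(row), col = col)
}

#' @rdname wellLabelToCoords
#' @param row,col integer coordinates (1-based).
#' @return \code{coordsToWellLabel}: character vector like "A01".
#' @export
coordsToWellLabel <- function(row, col) {
  lab <- vapply(row, function(r) {
    s <- ""
    while (r > 0L) {
      s <- paste0(LETTERS[(r - 1L) %% 26L + 1L], s)
      r <- (r - 1L) %/% 26L
    }
    s
  }, "")
  sprintf("%s%02d", lab, col)
}
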