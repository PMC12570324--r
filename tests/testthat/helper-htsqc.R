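# Shared fixture builders; everything is generated in code.

makeSeries <- function(conc, resp, compoundId = "cmp") {
  n <- length(conc)
  ord <- order(conc)
  new("DoseSeries",
    compoundId = compoundId,
    points = data.frame(
      concentration = conc[ord], response = resp[ord],
      row = rep(1L, n), col = seq_len(n)
    )
  )
}

# Minimal hand-laid plate: nSeries compounds across a row each, controls in
# the first and last column.
makeTinyPlate <- function(responses, conc = 10^seq(-2, 1.5, 0.5),
                          plateId = "tiny", nRows = 8L, nCols = 12L) {
  nd <- length(conc)
  stopifnot(is.list(responses), all(lengths(responses) == nd))
  rows <- list()
  for (i in seq_along(responses)) {
    rows[[i]] <- data.frame(
      row = i, col = 1L + seq_len(nd), wellType = "compound",
      compoundId = sprintf("cmp%02d", i), concentration = conc,
      response = responses[[i]]
    )
  }
  ctrl <- data.frame(
    row = rep(seq_len(4L), 2L),
    col = rep(c(1L, nCols), each = 4L),
    wellType = rep(c("neg_ctrl", "pos_ctrl"), each = 4L),
    compoundId = NA_character_, concentration = NA_real_,
    response = rep(c(0, 100), each = 4L)
  )
  PlateData(plateId, rbind(do.call(rbind, rows), ctrl), nRows = nRows, nCols = nCols)
}

# Literal reconstruction of the NRFE double sum from a plate's fits,
# independent of plateNRFE's vectorised path.
bruteForceNRFE <- function(fits) {
  ok <- Filter(function(f) fitStatus(f) != "failed", fits)
  total <- 0
  for (f in ok) {
    ni <- length(f@residuals)
    inner <- 0
    for (j in seq_len(ni)) {
      p <- min(max(f@fitted[j] / 100, 0), 1)
      k <- 1 + p * (1 - p) / 0.25
      inner <- inner + abs(f@residuals[j] * k)
    }
    total <- total + inner / ni
  }
  total / length(ok)
}
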