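#' Construct a PlateData object
#'
#' @param plateId plate identifier.
#' @param nRows,nCols plate geometry; the common shorthands
#'   \code{geometry = 96} (8 x 12) and \code{geometry = 384} (16 x 24) are
#'   available through [plateGeometry()].
#' @param wells data.frame with columns \code{row}, \code{col},
#'   \code{wellType}, \code{compoundId}, \code{concentration} (micromolar),
#'   \code{response} (percent inhibition).
#' @param metadata optional named list.
#' @return a validated [PlateData-class] object.
#' @examples
#' w <- data.frame(
#'   row = 1L, col = 1:3,
#'   wellType = c("neg_ctrl", "compound", "pos_ctrl"),
#'   compoundId = c(NA, "drugA", NA),
#'   concentration = c(NA, 1, NA),
#'   response = c(2, 55, 98)
#' )
#' PlateData("P1", wells = w, nRows = 8L, nCols = 12L)
#' @export
PlateData <- function(plateId, wells, nRows = 8L, nCols = 12L, metadata = list()) {
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  wells$wellType <- as.character(wells$wellType)
  wells$compoundId <- as.character(wells$compoundId)
  wells$concentration <- as.numeric(wells$concentration)
  wells$response <- as.numeric(wells$response)
  rownames(wells) <- NULL
  new("PlateData",
    plateId = as.character(plateId), nRows = as.integer(nRows),
    nCols = as.integer(nCols), wells = wells, metadata = metadata
  )
}

#' Standard plate geometries
#'
#' @param geometry 96 or 384.
#' @return c(nRows, nCols): 8 x 12 for 96-well, 16 x 24 for 384-well.
#' @export
plateGeometry <- function(geometry) {
  switch(as.character(geometry),
    "96" = c(8L, 12L),
    "384" = c(16L, 24L),
    .htsqcError("geometry must be 96 or 384", "configError")
  )
}

#' Partition a plate's compound wells into dose series
#'
#' Produces one [DoseSeries-class] per distinct compound on the plate.
#' Every compound well lands in exactly one series (the partition is
#' lossless); within a series, points are sorted by ascending
#' concentration and replicate measurements at the same concentration are
#' kept as separate points.
#'
#' @param plate a [PlateData-class].
#' @return named list of [DoseSeries-class], in order of first appearance.
#' @export
extractDoseSeries <- function(plate) {
  stopifnot(is(plate, "PlateData"))
  w <- wellData(plate)
  cw <- w[w$wellType == "compound", , drop = FALSE]
  if (nrow(cw) == 0L) {
    .htsqcError(
      sprintf("plate '%s' has no compound wells", plateId(plate)),
      "emptyPlateError"
    )
  }
  ids <- unique(cw$compoundId)
  out <- lapply(ids, function(id) {
    p <- cw[cw$compoundId == id, c("concentration", "response", "row", "col")]
    p <- p[order(p$concentration, p$row, p$col), , drop = FALSE]
    rownames(p) <- NULL
    new("DoseSeries", compoundId = id, points = p)
  })
  names(out) <- ids
  out
}

#' Summarize a plate's control wells
#'
#' Computes mean / sample (n-1) standard deviation and median /
#' normal-consistent MAD of the positive and negative control responses.
#' Depends only on the control response values, not their positions.
#'
#' @param plate a [PlateData-class] with at least 2 wells of each control
#'   type; fewer raises an insufficient-controls error (the
#'   control-independent NRFE remains computable via [plateQC()], which
#'   catches this condition).
#' @return a [ControlSummary-class].
#' @export
summarizeControls <- function(plate) {
  stopifnot(is(plate, "PlateData"))
  w <- wellData(plate)
  pos <- w$response[w$wellType == "pos_ctrl"]
  neg <- w$response[w$wellType == "neg_ctrl"]
  if (length(pos) < 2L || length(neg) < 2L) {
    .htsqcError(
      sprintf(
        "plate '%s' has %d positive / %d negative control wells; >= 2 of each are required",
        plateId(plate), length(pos), length(neg)
      ),
      "insufficientControlsError"
    )
  }
  new("ControlSummary",
    muP = mean(pos), sigmaP = stats::sd(pos),
    muN = mean(neg), sigmaN = stats::sd(neg),
    medP = stats::median(pos), madP = stats::mad(pos),
    medN = stats::median(neg), madN = stats::mad(neg),
    nPos = length(pos), nNeg = length(neg)
  )
}

#' Build a ControlSummary from explicit statistics
#'
#' Convenience constructor used when control statistics are already known
#' (e.g. metric golden-value checks or imported summaries).
#'
#' @param muP,sigmaP,muN,sigmaN mean / sd of positive and negative
#'   controls.
#' @param medP,madP,medN,madN robust analogues; default to the moment
#'   statistics.
#' @param nPos,nNeg control counts (default 2, the minimum).
#' @return a [ControlSummary-class].
#' @export
ControlSummary <- function(muP, sigmaP, muN, sigmaN,
                           medP = muP, madP = sigmaP,
                           medN = muN, madN = sigmaN,
                           nPos = 2L, nNeg = 2L) {
  new("ControlSummary",
    muP = muP, sigmaP = sigmaP, muN = muN, sigmaN = sigmaN,
    medP = medP, madP = madP, medN = medN, madN = madN,
    nPos = as.integer(nPos), nNeg = as.integer(nNeg)
  )
}

#' @rdname accessors
#' @export
setGeneric("nDoseSeries", function(object) standardGeneric("nDoseSeries"))

#' @rdname accessors
#' @export
setMethod("nDoseSeries", "PlateData", function(object) {
  w <- object@wells
  length(unique(w$compoundId[w$wellType == "compound"]))
})

#' @rdname accessors
#' @export
setGeneric("seriesPoints", function(object) standardGeneric("seriesPoints"))

#' @rdname accessors
#' @export
setMethod("seriesPoints", "DoseSeries", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("compoundId", function(object) standardGeneric("compoundId"))

#' @rdname accessors
#' @export
setMethod("compoundId", "DoseSeries", function(object) object@compoundId)
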