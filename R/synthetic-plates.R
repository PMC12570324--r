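#' Configuration for the synthetic plate generator
#'
#' Describes one simulated multi-dose screening plate. The generated
#' layout follows common screening practice: negative controls in the
#' left-most column block, positive controls in the right-most, and
#' compound dose series laid \emph{horizontally} -- doses ascend along
#' columns within a row -- so that column-wise liquid-handling artifacts
#' corrupt the shape of dose-response curves rather than shifting whole
#' series uniformly.
#'
#' \itemize{
#'   \item 96-well (8 x 12): negative controls col 1, positive col 12,
#'     compounds in cols 2-11; with 10 doses per compound, one series per
#'     row (8 series).
#'   \item 384-well (16 x 24): negative controls cols 1-2, positive cols
#'     23-24, compounds in cols 3-22; with 10 doses, two series per row
#'     (32 series).
#' }
#'
#' @param geometry 96 or 384 (default 384).
#' @param dosesPerCompound doses per series on a half-log ladder
#'   (default 10).
#' @param maxDose top concentration, micromolar (default 10; the ladder is
#'   maxDose * 10^(-0.5 k)).
#' @param nCompounds number of series to place; default fills the layout.
#' @param paramRanges uniform draw ranges for the true LL4 parameters:
#'   list(a=, d=, b=, lc=) where lc is log10 IC50 (micromolar). Defaults
#'   give near-zero baselines, variable efficacy (d in 40-100), slopes in
#'   0.5-3 and IC50s well inside the tested range (active compounds, so
#'   noiseless plates are exactly model-consistent).
#' @param noiseSd i.i.d. Gaussian well noise, percent inhibition
#'   (default 5).
#' @param seed integer seed; identical config + seed gives identical
#'   plates.
#' @return a list of class \code{"PlateSimConfig"}.
#' @export
plateSimConfig <- function(geometry = 384, dosesPerCompound = 10L,
                           maxDose = 10, nCompounds = NULL,
                           paramRanges = list(
                             a = c(-2, 5), d = c(40, 100),
                             b = c(0.5, 3), lc = NULL
                           ),
                           noiseSd = 5, seed = NULL) {
  dims <- plateGeometry(geometry)
  layout <- .plateLayout(geometry, dims)
  doses <- as.integer(dosesPerCompound)
  if (doses < 2L) .htsqcError("dosesPerCompound must be >= 2", "configError")
  perRow <- length(layout$compoundCols) %/% doses
  if (perRow < 1L) {
    .htsqcError("dose series does not fit in the compound column block", "configError")
  }
  capacity <- perRow * dims[1]
  if (is.null(nCompounds)) nCompounds <- capacity
  if (nCompounds > capacity) {
    .htsqcError(
      sprintf("layout holds at most %d series of %d doses", capacity, doses),
      "configError"
    )
  }
  if (noiseSd < 0) .htsqcError("noiseSd must be >= 0", "configError")
  conc <- maxDose * 10^(-0.5 * (doses - seq_len(doses)))
  ## default IC50 draws sit well inside the tested ladder so every series
  ## traverses a usable fraction of its dynamic range (active compounds)
  if (is.null(paramRanges$lc)) {
    paramRanges$lc <- log10(range(conc)) + c(0.75, -1)
  }
  structure(
    list(
      geometry = geometry, nRows = dims[1], nCols = dims[2],
      layout = layout, dosesPerCompound = doses,
      concentrations = conc, nCompounds = as.integer(nCompounds),
      seriesPerRow = perRow, paramRanges = paramRanges,
      noiseSd = noiseSd, seed = seed
    ),
    class = "PlateSimConfig"
  )
}

.plateLayout <- function(geometry, dims) {
  if (geometry == 96) {
    list(negCols = 1L, posCols = 12L, compoundCols = 2:11)
  } else {
    list(negCols = 1:2, posCols = 23:24, compoundCols = 3:22)
  }
}

#' Simulate one screening plate with known ground truth
#'
#' Compound responses are LL4(x; true parameters) plus i.i.d. Gaussian
#' noise; negative controls are N(0, noiseSd^2), positive controls
#' N(100, noiseSd^2), on the percent-inhibition scale. Fully
#' deterministic given (config, seed): the RNG state of the caller is
#' never touched.
#'
#' @param config a [plateSimConfig()].
#' @param plateId identifier for the generated plate.
#' @param seed overrides \code{config$seed} when given.
#' @return list with elements \code{plate} (a [PlateData-class]) and
#'   \code{truth} (list: \code{params} data.frame of true per-compound
#'   a, d, b, c; \code{muN}, \code{muP}, \code{noiseSd}).
#' @examples
#' sim <- simulatePlate(plateSimConfig(geometry = 96, seed = 7))
#' sim$plate
#' @export
simulatePlate <- function(config, plateId = "simulated-1", seed = config$seed) {
  stopifnot(inherits(config, "PlateSimConfig"))
  withLocalSeed(seed, {
    lay <- config$layout
    pr <- config$paramRanges
    n <- config$nCompounds
    params <- data.frame(
      compoundId = sprintf("C%03d", seq_len(n)),
      a = stats::runif(n, pr$a[1], pr$a[2]),
      d = stats::runif(n, pr$d[1], pr$d[2]),
      b = stats::runif(n, pr$b[1], pr$b[2]),
      c = 10^stats::runif(n, pr$lc[1], pr$lc[2])
    )
    doses <- config$dosesPerCompound
    rows <- integer(0); cols <- integer(0)
    type <- character(0); cid <- character(0); conc <- numeric(0); resp <- numeric(0)
    k <- 0L
    for (r in seq_len(config$nRows)) {
      for (s in seq_len(config$seriesPerRow)) {
        if (k >= n) break
        k <- k + 1L
        cc <- lay$compoundCols[((s - 1L) * doses + 1L):(s * doses)]
        mu <- ll4(config$concentrations, params$a[k], params$b[k], params$c[k], params$d[k])
        rows <- c(rows, rep(r, doses)); cols <- c(cols, cc)
        type <- c(type, rep("compound", doses))
        cid <- c(cid, rep(params$compoundId[k], doses))
        conc <- c(conc, config$concentrations)
        resp <- c(resp, mu + stats::rnorm(doses, 0, config$noiseSd))
      }
    }
    for (cset in list(c("neg_ctrl", 0, lay$negCols), c("pos_ctrl", 100, lay$posCols))) {
      ctype <- cset[[1]]; cmu <- as.numeric(cset[[2]])
      ccols <- as.integer(cset[-(1:2)])
      for (cl in ccols) {
        rows <- c(rows, seq_len(config$nRows)); cols <- c(cols, rep(cl, config$nRows))
        type <- c(type, rep(ctype, config$nRows))
        cid <- c(cid, rep(NA_character_, config$nRows))
        conc <- c(conc, rep(NA_real_, config$nRows))
        resp <- c(resp, stats::rnorm(config$nRows, cmu, config$noiseSd))
      }
    }
    plate <- PlateData(
      plateId = plateId,
      wells = data.frame(
        row = rows, col = cols, wellType = type,
        compoundId = cid, concentration = conc, response = resp,
        stringsAsFactors = FALSE
      ),
      nRows = config$nRows, nCols = config$nCols,
      metadata = list(simulated = TRUE, seed = seed)
    )
    list(plate = plate, truth = list(
      params = params, muN = 0, muP = 100, noiseSd = config$noiseSd
    ))
  })
}

#' Describe a spatial plate artifact
#'
#' @param kind "column_striping", "row_striping", "edge_effect" or
#'   "linear_gradient".
#' @param magnitude additive response shift, percent inhibition (for
#'   gradients, the shift at the far end of the ramp).
#' @param columns,rows affected columns / rows (striping kinds).
#' @param depth ring depth in wells for edge effects (default 1).
#' @param axis gradient axis, "col" or "row".
#' @param target "compound_only" (default: control wells untouched) or
#'   "all_wells".
#' @param rowGradient for \code{column_striping} only: when TRUE the
#'   shift ramps linearly with the well's row, from 0 in the first row to
#'   the full magnitude in the last -- a striping defect that worsens
#'   across the plate run, so different dose series are distorted by
#'   different amounts.
#' @return list of class \code{"ArtifactSpec"}.
#' @export
artifactSpec <- function(kind = c("column_striping", "row_striping",
                                  "edge_effect", "linear_gradient"),
                         magnitude, columns = NULL, rows = NULL,
                         depth = 1L, axis = c("col", "row"),
                         target = c("compound_only", "all_wells"),
                         rowGradient = FALSE) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  target <- match.arg(target)
  if (!is.finite(magnitude)) .htsqcError("magnitude must be finite", "configError")
  if (rowGradient && kind != "column_striping") {
    .htsqcError("rowGradient applies to column_striping only", "configError")
  }
  structure(
    list(
      kind = kind, magnitude = magnitude, columns = columns,
      rows = rows, depth = as.integer(depth), axis = axis, target = target,
      rowGradient = isTRUE(rowGradient)
    ),
    class = "ArtifactSpec"
  )
}

#' Inject a spatial artifact into a plate
#'
#' Shifts the responses of the wells in the artifact's region by the
#' given magnitude (striping and edge effects: constant additive shift;
#' linear gradients: a ramp from 0 at one plate edge to the magnitude at
#' the other). All artifacts act additively on the percent-inhibition
#' scale, emulating post-normalisation systematic errors such as
#' pipetting striping, edge evaporation and temperature/incubation
#' gradients. Wells outside the region are bit-identical to the input;
#' control wells are modified only when \code{target = "all_wells"}.
#'
#' @param plate a [PlateData-class].
#' @param spec an [artifactSpec()].
#' @return the modified [PlateData-class]; an empty affected region
#'   produces a warning and the unchanged plate.
#' @export
injectArtifact <- function(plate, spec) {
  stopifnot(is(plate, "PlateData"), inherits(spec, "ArtifactSpec"))
  w <- wellData(plate)
  dims <- plateDim(plate)
  inRegion <- switch(spec$kind,
    column_striping = {
      if (is.null(spec$columns)) .htsqcError("column_striping needs columns", "configError")
      if (any(spec$columns < 1L | spec$columns > dims[2])) {
        .htsqcError("striping columns outside plate geometry", "configError")
      }
      w$col %in% spec$columns
    },
    row_striping = {
      if (is.null(spec$rows)) .htsqcError("row_striping needs rows", "configError")
      if (any(spec$rows < 1L | spec$rows > dims[1])) {
        .htsqcError("striping rows outside plate geometry", "configError")
      }
      w$row %in% spec$rows
    },
    edge_effect = {
      d <- spec$depth
      w$row <= d | w$row > dims[1] - d | w$col <= d | w$col > dims[2] - d
    },
    linear_gradient = rep(TRUE, nrow(w))
  )
  if (spec$target == "compound_only") {
    inRegion <- inRegion & w$wellType == "compound"
  } else {
    inRegion <- inRegion & w$wellType != "empty"
  }
  if (!any(inRegion)) {
    warning("artifact region contains no affected wells; plate unchanged")
    return(plate)
  }
  shift <- if (spec$kind == "linear_gradient") {
    pos <- if (spec$axis == "col") w$col else w$row
    span <- if (spec$axis == "col") dims[2] else dims[1]
    spec$magnitude * (pos - 1) / max(span - 1, 1L)
  } else if (spec$kind == "column_striping" && isTRUE(spec$rowGradient)) {
    spec$magnitude * (w$row - 1) / max(dims[1] - 1, 1L)
  } else {
    rep(spec$magnitude, nrow(w))
  }
  w$response[inRegion] <- w$response[inRegion] + shift[inRegion]
  plate@wells <- w
  plate@metadata$artifacts <- c(plate@metadata$artifacts, list(spec))
  plate
}

## Default striping region for tier-targeted degradation: alternating
## compound columns (control-free by construction), the classic failure
## mode of a dispenser with misbehaving alternate tips. Alternating
## stripes interleave shifted and unshifted doses, producing the jumpy
## curves NRFE targets; a contiguous block aligned with the dose gradient
## would largely be absorbed by the fit's asymptotes.
.degradeColumns <- function(config) {
  cc <- config$layout$compoundCols
  cc[seq(2L, length(cc), by = 2L)]
}

#' Simulate a batch of paired replicate plates with a target tier mix
#'
#' Each pair measures the same compounds (identical ground-truth LL4
#' parameters) on two independently generated plates, emulating technical
#' replicate screens or the same experiment run in two datasets. A pair's
#' target quality tier is drawn from \code{tierMix}; pairs targeted at
#' "borderline" or "poor" have one side degraded by a column-striping
#' artifact that worsens across rows (\code{rowGradient}), so series in
#' different rows are distorted by different amounts -- degraded plates
#' lose replicate agreement, not just accuracy. The magnitude is steered
#' (bounded retries) until the plate's measured NRFE lands in the
#' requested tier.
#'
#' @param config a [plateSimConfig()]; 96-well with 10 doses gives 8
#'   series (pairs of measurements) per plate pair.
#' @param nPairs number of plate pairs.
#' @param tierMix named proportions over
#'   c("acceptable", "borderline", "poor"); must sum to 1.
#' @param seed master seed; every draw derives from it.
#' @param maxRetries magnitude steering steps (including noise redraws)
#'   allowed per degraded plate before a simulation error.
#' @return list with \code{pairTable} (pairId, plateId1, plateId2,
#'   targetTier, magnitude), \code{plates} (named list of
#'   [PlateData-class]), and \code{results}: one row per dose series per
#'   plate with sampleId, compoundId, nDoses, auc, dss, ic50,
#'   ic50Reached, plate nrfe, zPrime and tier -- the long table consumed
#'   by [pairReplicates()].
#' @export
simulateReplicateBatch <- function(config, nPairs,
                                   tierMix = c(acceptable = 0.6, borderline = 0.25, poor = 0.15),
                                   seed = 1L, maxRetries = 30L) {
  stopifnot(inherits(config, "PlateSimConfig"))
  if (abs(sum(tierMix) - 1) > 1e-8) {
    .htsqcError("tierMix proportions must sum to 1", "configError")
  }
  if (nPairs == 0L) {
    return(list(
      pairTable = data.frame(), plates = list(),
      results = data.frame()
    ))
  }
  tiers <- names(tierMix)
  stopifnot(all(tiers %in% .TIERS))
  ## deterministic tier allocation proportional to the mix
  alloc <- rep(tiers, times = diff(round(cumsum(c(0, tierMix)) * nPairs)))
  if (length(alloc) < nPairs) alloc <- c(alloc, rep(tiers[1], nPairs - length(alloc)))
  magRange <- list(borderline = c(12, 18), poor = c(25, 60))
  stripeCols <- .degradeColumns(config)

  plates <- list(); rowsOut <- list(); pairRows <- list()
  for (i in seq_len(nPairs)) {
    target <- alloc[i]
    ## both plates of a pair share the compound ground truth: regenerate
    ## with the same parameter draws but independent noise
    truthSeed <- subSeed(seed, i * 3L)
    base <- plateSimConfig(
      geometry = config$geometry,
      dosesPerCompound = config$dosesPerCompound,
      maxDose = max(config$concentrations),
      nCompounds = config$nCompounds,
      paramRanges = config$paramRanges,
      noiseSd = config$noiseSd
    )
    truth <- withLocalSeed(truthSeed, {
      pr <- base$paramRanges; n <- base$nCompounds
      data.frame(
        a = stats::runif(n, pr$a[1], pr$a[2]),
        d = stats::runif(n, pr$d[1], pr$d[2]),
        b = stats::runif(n, pr$b[1], pr$b[2]),
        c = 10^stats::runif(n, pr$lc[1], pr$lc[2])
      )
    })
    mag <- NA_real_
    for (rep_k in 1:2) {
      pid <- sprintf("P%04d-%d", i, rep_k)
      noiseSeed <- subSeed(seed, i * 3L + rep_k)
      sim <- .simulateFromTruth(base, truth, pid, noiseSeed)
      degrade <- rep_k == 2L && target != "acceptable"
      if (!degrade) {
        plate <- sim
        qc <- plateQC(plate, returnFits = TRUE)
      } else {
        ok <- FALSE
        targetNrfe <- if (target == "borderline") 12.5 else 20
        tRank <- match(target, .TIERS)
        degSim <- sim
        m <- withLocalSeed(subSeed(noiseSeed, 7L), {
          stats::runif(1, magRange[[target]][1], magRange[[target]][2])
        })
        lo <- 0; hi <- Inf
        for (try_k in seq_len(maxRetries)) {
          cand <- injectArtifact(degSim, artifactSpec(
            "column_striping", magnitude = m, columns = stripeCols,
            rowGradient = TRUE
          ))
          qcCand <- plateQC(cand, returnFits = TRUE)
          tierK <- qcTier(qcCand)
          if (tierK == target) {
            plate <- cand; qc <- qcCand; mag <- m; ok <- TRUE
            break
          }
          ## bracket the tier band, then bisect; when the bracket
          ## collapses the NRFE response has a jump that skips the band
          ## for this noise draw -- redraw the degraded side's noise
          ## (an equally valid independent replicate) and restart
          if (match(tierK, .TIERS) < tRank) lo <- max(lo, m) else hi <- min(hi, m)
          if (hi - lo < 0.05) {
            degSim <- .simulateFromTruth(base, truth, pid, subSeed(noiseSeed, 997L + try_k))
            lo <- 0; hi <- Inf
          } else if (is.finite(hi)) {
            m <- (lo + hi) / 2
          } else {
            m <- .clamp(m * (targetNrfe / max(nrfe(qcCand), 0.5))^0.8, 0.5, 120)
          }
        }
        if (!ok) {
          .htsqcError(
            sprintf("pair %d: could not reach tier '%s' in %d retries", i, target, maxRetries),
            "simulationError"
          )
        }
      }
      plates[[plateId(plate)]] <- plate
      met <- plateSeriesMetrics(plate, qc)
      met$pairId <- i
      met$replicate <- rep_k
      met$sampleId <- sprintf("S%04d", i)
      rowsOut[[length(rowsOut) + 1L]] <- met
    }
    pairRows[[i]] <- data.frame(
      pairId = i, plateId1 = sprintf("P%04d-1", i), plateId2 = sprintf("P%04d-2", i),
      targetTier = target, magnitude = mag
    )
  }
  list(
    pairTable = do.call(rbind, pairRows),
    plates = plates,
    results = do.call(rbind, rowsOut)
  )
}

## Regenerate a plate from pre-drawn truth parameters with fresh noise.
.simulateFromTruth <- function(config, truth, plateId, noiseSeed) {
  withLocalSeed(noiseSeed, {
    lay <- config$layout
    doses <- config$dosesPerCompound
    n <- config$nCompounds
    rows <- integer(0); cols <- integer(0)
    type <- character(0); cid <- character(0); conc <- numeric(0); resp <- numeric(0)
    k <- 0L
    for (r in seq_len(config$nRows)) {
      for (s in seq_len(config$seriesPerRow)) {
        if (k >= n) break
        k <- k + 1L
        cc <- lay$compoundCols[((s - 1L) * doses + 1L):(s * doses)]
        mu <- ll4(config$concentrations, truth$a[k], truth$b[k], truth$c[k], truth$d[k])
        rows <- c(rows, rep(r, doses)); cols <- c(cols, cc)
        type <- c(type, rep("compound", doses))
        cid <- c(cid, rep(sprintf("C%03d", k), doses))
        conc <- c(conc, config$concentrations)
        resp <- c(resp, mu + stats::rnorm(doses, 0, config$noiseSd))
      }
    }
    for (cset in list(list("neg_ctrl", 0, lay$negCols), list("pos_ctrl", 100, lay$posCols))) {
      for (cl in cset[[3]]) {
        rows <- c(rows, seq_len(config$nRows)); cols <- c(cols, rep(cl, config$nRows))
        type <- c(type, rep(cset[[1]], config$nRows))
        cid <- c(cid, rep(NA_character_, config$nRows))
        conc <- c(conc, rep(NA_real_, config$nRows))
        resp <- c(resp, stats::rnorm(config$nRows, cset[[2]], config$noiseSd))
      }
    }
    PlateData(
      plateId = plateId,
      wells = data.frame(
        row = rows, col = cols, wellType = type,
        compoundId = cid, concentration = conc, response = resp,
        stringsAsFactors = FALSE
      ),
      nRows = config$nRows, nCols = config$nCols,
      metadata = list(simulated = TRUE, seed = noiseSeed)
    )
  })
}

#' Per-series response metrics plus plate QC, as one long table
#'
#' @param plate a [PlateData-class].
#' @param qc its [PlateQCResult-class] from \code{plateQC(...,
#'   returnFits = TRUE)}; computed on the fly when missing.
#' @return data.frame with one row per fitted dose series.
#' @export
plateSeriesMetrics <- function(plate, qc = NULL) {
  if (is.null(qc)) qc <- plateQC(plate, returnFits = TRUE)
  fits <- attr(qc, "fits")
  stopifnot(!is.null(fits))
  series <- extractDoseSeries(plate)
  zp <- qc@controlMetrics$z_prime
  out <- lapply(names(fits), function(id) {
    rm_ <- computeResponseMetrics(fits[[id]], series[[id]])
    data.frame(
      plateId = plateId(plate), compoundId = id,
      nDoses = length(unique(seriesPoints(series[[id]])$concentration)),
      auc = rm_$auc, dss = rm_$dss,
      ic50 = as.numeric(rm_$ic50), ic50Reached = rm_$ic50Reached,
      nrfe = nrfe(qc), zPrime = if (is.null(zp)) NA_real_ else as.numeric(zp),
      tier = qcTier(qc),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
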