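#' Pair replicate measurements of the same compound-sample combination
#'
#' From a long table of per-series results (as produced by
#' [plateSeriesMetrics()] / [simulateReplicateBatch()]), retains only
#' (compoundId, sampleId) combinations that were measured on exactly two
#' distinct plates, with more than \code{minDoses} concentrations on both
#' sides -- the filters under which replicate dose-response comparisons
#' are reliable. Exclusion counts are attached as attribute
#' \code{"exclusions"}.
#'
#' @param results data.frame with columns plateId, compoundId, sampleId,
#'   nDoses, auc, dss, ic50, ic50Reached, nrfe, zPrime, tier.
#' @param minDoses series on both sides must have strictly more than this
#'   many distinct concentrations (default 3).
#' @return data.frame of matched pairs, one row per retained combination,
#'   with suffixed columns (\code{auc1}/\code{auc2}, ..., \code{nrfe1},
#'   \code{zPrime1}, \code{tier1}, ...).
#' @export
pairReplicates <- function(results, minDoses = 3L) {
  stopifnot(all(c("plateId", "compoundId", "sampleId", "nDoses") %in% names(results)))
  if (nrow(results) == 0L) {
    out <- data.frame()
    attr(out, "exclusions") <- c(not_two_plates = 0L, too_few_doses = 0L)
    return(out)
  }
  key <- paste(results$compoundId, results$sampleId, sep = "\r")
  nPlates <- tapply(results$plateId, key, function(p) length(unique(p)))
  twoPlates <- names(nPlates)[nPlates == 2L]
  nNotTwo <- sum(nPlates != 2L)
  keep <- results[key %in% twoPlates, , drop = FALSE]
  key2 <- paste(keep$compoundId, keep$sampleId, sep = "\r")
  nTooFew <- 0L
  rowsOut <- lapply(unique(key2), function(k) {
    g <- keep[key2 == k, , drop = FALSE]
    g <- g[order(g$plateId), , drop = FALSE]
    if (any(g$nDoses <= minDoses)) {
      nTooFew <<- nTooFew + 1L
      return(NULL)
    }
    cbind(
      data.frame(compoundId = g$compoundId[1], sampleId = g$sampleId[1]),
      stats::setNames(g[1, c("plateId", "auc", "dss", "ic50", "ic50Reached", "nrfe", "zPrime", "tier")],
        paste0(c("plateId", "auc", "dss", "ic50", "ic50Reached", "nrfe", "zPrime", "tier"), "1")),
      stats::setNames(g[2, c("plateId", "auc", "dss", "ic50", "ic50Reached", "nrfe", "zPrime", "tier")],
        paste0(c("plateId", "auc", "dss", "ic50", "ic50Reached", "nrfe", "zPrime", "tier"), "2"))
    )
  })
  out <- do.call(rbind, rowsOut)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(not_two_plates = nNotTwo, too_few_doses = nTooFew)
  out
}

.worstTier <- function(t1, t2) {
  r <- pmax(match(t1, .TIERS), match(t2, .TIERS))
  .TIERS[r]
}

#' Replicate deltas stratified by plate quality tier
#'
#' Each matched pair is assigned to the worst tier of its two plates.
#' Within every stratum, the absolute replicate differences |dAUC|,
#' |dDSS| and |d log10 IC50| are summarised (median, IQR, n); strata are
#' compared against the "acceptable" stratum with two-sided Wilcoxon
#' rank-sum tests on |dAUC|. IC50 deltas are taken on the log10 scale and
#' only over pairs where both sides reached their IC50.
#'
#' @param pairs data.frame from [pairReplicates()].
#' @return list with \code{summary} (data.frame: tier, n, medianAbsDAuc,
#'   iqrAbsDAuc, medianAbsDDss, medianAbsDLogIc50, insufficient) and
#'   \code{tests} (data.frame of Wilcoxon p-values vs the acceptable
#'   stratum). Strata with fewer than 2 pairs are marked insufficient.
#' @export
tierStratifiedDeltas <- function(pairs) {
  stopifnot(nrow(pairs) > 0L)
  tier <- .worstTier(pairs$tier1, pairs$tier2)
  dAuc <- abs(pairs$auc1 - pairs$auc2)
  dDss <- abs(pairs$dss1 - pairs$dss2)
  dIc50 <- ifelse(pairs$ic50Reached1 & pairs$ic50Reached2,
    abs(log10(pairs$ic501) - log10(pairs$ic502)), NA_real_
  )
  summ <- do.call(rbind, lapply(.TIERS, function(t) {
    i <- tier == t
    n <- sum(i)
    if (n < 2L) {
      return(data.frame(
        tier = t, n = n, medianAbsDAuc = NA_real_, iqrAbsDAuc = NA_real_,
        medianAbsDDss = NA_real_, medianAbsDLogIc50 = NA_real_,
        insufficient = TRUE
      ))
    }
    data.frame(
      tier = t, n = n,
      medianAbsDAuc = stats::median(dAuc[i]),
      iqrAbsDAuc = stats::IQR(dAuc[i]),
      medianAbsDDss = stats::median(dDss[i]),
      medianAbsDLogIc50 = stats::median(dIc50[i], na.rm = TRUE),
      insufficient = FALSE
    )
  }))
  ref <- tier == "acceptable"
  tests <- do.call(rbind, lapply(c("borderline", "poor"), function(t) {
    i <- tier == t
    p <- if (sum(i) >= 2L && sum(ref) >= 2L) {
      stats::wilcox.test(dAuc[i], dAuc[ref])$p.value
    } else {
      NA_real_
    }
    data.frame(comparison = paste(t, "vs acceptable"), pValue = p)
  }))
  list(summary = summ, tests = tests, strata = tier)
}

#' Correlation grids over joint quality-threshold sweeps
#'
#' For every combination of a Z-prime threshold zt and an NRFE threshold
#' nt, splits the matched pairs into a good-quality subset (both sides
#' with zPrime > zt AND nrfe < nt) and a poor-quality subset (either side
#' failing either bound) and computes the Spearman correlation of
#' \code{metric} between the two sides within each subset. Cells with
#' fewer than \code{minPairs} pairs are masked (NA).
#'
#' @param pairs data.frame from [pairReplicates()].
#' @param zGrid,nrfeGrid numeric threshold grids (both non-empty).
#' @param metric which per-series metric to correlate (default "dss").
#' @param minPairs cell mask threshold (default 10).
#' @return list of matrices \code{rhoGood}, \code{rhoPoor},
#'   \code{nGood}, \code{nPoor} (rows = zGrid, cols = nrfeGrid), plus
#'   \code{baselineRho} over all pairs.
#' @export
thresholdSweep <- function(pairs, zGrid, nrfeGrid, metric = "dss", minPairs = 10L) {
  if (length(zGrid) == 0L || length(nrfeGrid) == 0L) {
    .htsqcError("threshold grids must be non-empty", "configError")
  }
  if (nrow(pairs) < 10L) {
    .htsqcError("threshold sweep needs at least 10 pairs", "configError")
  }
  v1 <- pairs[[paste0(metric, "1")]]
  v2 <- pairs[[paste0(metric, "2")]]
  baseline <- stats::cor(v1, v2, method = "spearman")
  dimn <- list(sprintf("z>%.3g", zGrid), sprintf("nrfe<%.3g", nrfeGrid))
  mk <- function() matrix(NA_real_, length(zGrid), length(nrfeGrid), dimnames = dimn)
  rhoGood <- mk(); rhoPoor <- mk()
  nGood <- mk(); nPoor <- mk()
  for (i in seq_along(zGrid)) {
    for (j in seq_along(nrfeGrid)) {
      good <- pairs$zPrime1 > zGrid[i] & pairs$zPrime2 > zGrid[i] &
        pairs$nrfe1 < nrfeGrid[j] & pairs$nrfe2 < nrfeGrid[j]
      nGood[i, j] <- sum(good)
      nPoor[i, j] <- sum(!good)
      if (sum(good) >= minPairs) {
        rhoGood[i, j] <- stats::cor(v1[good], v2[good], method = "spearman")
      }
      if (sum(!good) >= minPairs) {
        rhoPoor[i, j] <- stats::cor(v1[!good], v2[!good], method = "spearman")
      }
    }
  }
  list(
    rhoGood = rhoGood, rhoPoor = rhoPoor, nGood = nGood, nPoor = nPoor,
    baselineRho = baseline
  )
}

#' Bootstrap reference distribution of the Spearman correlation
#'
#' Resamples the matched pairs jointly (with replacement, 10,000 times by
#' default) and records the Spearman correlation of each resample,
#' yielding the reference distribution of the baseline consistency.
#' Average ranks handle ties. Deterministic under \code{seed}; the
#' caller's RNG state is untouched.
#'
#' @param x,y paired metric vectors of equal length (>= 10).
#' @param nBoot number of resamples (default 10000).
#' @param seed integer seed.
#' @return numeric vector of length nBoot.
#' @export
bootstrapReference <- function(x, y, nBoot = 10000L, seed = 1L) {
  if (length(x) != length(y)) {
    .htsqcError("x and y must have equal length", "contractViolation")
  }
  if (length(x) < 10L) {
    .htsqcError("bootstrap needs at least 10 pairs", "contractViolation")
  }
  n <- length(x)
  withLocalSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      stats::cor(x[i], y[i], method = "spearman")
    }, 0)
  })
}

#' Compare a correlation distribution against a bootstrap reference
#'
#' Two-sample Kolmogorov-Smirnov test plus the standardized mean
#' difference (difference in means divided by the pooled standard
#' deviation) between a quality-group distribution and the reference
#' distribution.
#'
#' @param referenceDist,groupDist numeric vectors (each >= 10 values).
#' @return list: \code{ksStatistic}, \code{ksP}, \code{effectSize} (an
#'   undefined marker when both distributions are degenerate).
#' @export
compareToReference <- function(referenceDist, groupDist) {
  if (length(referenceDist) < 10L || length(groupDist) < 10L) {
    .htsqcError("both distributions need >= 10 values", "contractViolation")
  }
  ks <- suppressWarnings(stats::ks.test(groupDist, referenceDist))
  v1 <- stats::var(referenceDist)
  v2 <- stats::var(groupDist)
  n1 <- length(referenceDist); n2 <- length(groupDist)
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  es <- if (pooled == 0) {
    undefinedMetric("zero variance in both distributions")
  } else {
    (mean(groupDist) - mean(referenceDist)) / pooled
  }
  list(
    ksStatistic = unname(ks$statistic),
    ksP = ks$p.value,
    effectSize = es
  )
}

#' Derive a batch-specific NRFE threshold
#'
#' The three-standard-deviations rule: mean + 3 sd of a batch's plate
#' NRFE distribution (or, robustly, median + 3 normal-consistent MAD),
#' the rule under which the default 10 / 15 tier cutoffs were derived
#' from large public screens.
#'
#' @param nrfeValues plate NRFE values, length >= 30.
#' @param robust use median + 3 MAD instead of mean + 3 sd.
#' @return the threshold.
#' @export
deriveThreshold <- function(nrfeValues, robust = FALSE) {
  if (length(nrfeValues) < 30L) {
    .htsqcError("threshold derivation needs >= 30 plate NRFE values", "insufficientDataError")
  }
  if (robust) {
    stats::median(nrfeValues) + 3 * stats::mad(nrfeValues)
  } else {
    mean(nrfeValues) + 3 * stats::sd(nrfeValues)
  }
}

#' Full consistency report for a matched-pair set
#'
#' Convenience wrapper: baseline Spearman/Pearson correlations,
#' tier-stratified deltas, bootstrap reference distribution and KS / SMD
#' comparisons of the good and poor quality groups (thresholds: good =
#' zPrime > zGood and nrfe < nrfeGood on both sides; poor = zPrime <
#' zPoor or nrfe > nrfePoor on either side).
#'
#' @param pairs data.frame from [pairReplicates()].
#' @param metric metric to correlate (default "dss").
#' @param zGood,nrfeGood,zPoor,nrfePoor quality thresholds (defaults 0.5,
#'   10, 0, 15).
#' @param nBoot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list of class \code{"ConsistencyReport"}.
#' @export
consistencyReport <- function(pairs, metric = "dss",
                              zGood = 0.5, nrfeGood = 10,
                              zPoor = 0, nrfePoor = 15,
                              nBoot = 10000L, seed = 1L) {
  v1 <- pairs[[paste0(metric, "1")]]
  v2 <- pairs[[paste0(metric, "2")]]
  good <- pairs$zPrime1 > zGood & pairs$zPrime2 > zGood &
    pairs$nrfe1 < nrfeGood & pairs$nrfe2 < nrfeGood
  poor <- pairs$zPrime1 < zPoor | pairs$zPrime2 < zPoor |
    pairs$nrfe1 > nrfePoor | pairs$nrfe2 > nrfePoor
  rho <- function(i) {
    if (sum(i) < 3L) return(NA_real_)
    stats::cor(v1[i], v2[i], method = "spearman")
  }
  rr <- function(i) {
    if (sum(i) < 3L) return(NA_real_)
    stats::cor(v1[i], v2[i], method = "pearson")
  }
  all_ <- rep(TRUE, nrow(pairs))
  boot <- bootstrapReference(v1, v2, nBoot = nBoot, seed = seed)
  structure(
    list(
      nPairs = nrow(pairs),
      spearmanRho = rho(all_), pearsonR = rr(all_),
      rhoGood = rho(good), rhoPoor = rho(poor),
      nGood = sum(good), nPoor = sum(poor),
      tierDeltas = tierStratifiedDeltas(pairs),
      bootstrap = boot,
      thresholds = c(zGood = zGood, nrfeGood = nrfeGood, zPoor = zPoor, nrfePoor = nrfePoor)
    ),
    class = "ConsistencyReport"
  )
}

#' @export
print.ConsistencyReport <- function(x, ...) {
  cat(sprintf(
    "ConsistencyReport: %d matched pairs\n  baseline rho = %.3f (Pearson r = %.3f)\n  good-quality rho = %.3f (n = %d), poor-quality rho = %.3f (n = %d)\n  bootstrap: %d resamples, mean rho = %.3f\n",
    x$nPairs, x$spearmanRho, x$pearsonR,
    x$rhoGood, x$nGood, x$rhoPoor, x$nPoor,
    length(x$bootstrap), mean(x$bootstrap)
  ))
  invisible(x)
}
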