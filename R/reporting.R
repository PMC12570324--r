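#' Plate heatmaps for inhibition and residual diagnostics
#'
#' Geometry-true well grid (row 1 at the top, as on the bench).
#' \code{mode = "inhibition"} colors raw percent inhibition;
#' \code{mode = "residual"} colors the scaled residual |eps * k| per
#' compound well -- the per-well contribution to NRFE -- which makes
#' spatial artifact patterns (striping, edge rings, gradients) directly
#' visible. Control wells are outlined. Output is deterministic for a
#' fixed input.
#'
#' @param plate a [PlateData-class].
#' @param mode "inhibition" or "residual".
#' @param fits named list of [LL4Fit-class] (required for residual mode;
#'   computed from the plate when NULL).
#' @param file optional path; when given the figure is written there
#'   (PNG/SVG by extension, via [ggplot2::ggsave()]) and the path is
#'   returned invisibly.
#' @return a ggplot object (or the file path when \code{file} is given).
#' @export
renderPlateHeatmap <- function(plate, mode = c("inhibition", "residual"),
                               fits = NULL, file = NULL) {
  stopifnot(is(plate, "PlateData"))
  mode <- match.arg(mode)
  w <- wellData(plate)
  if (nrow(w) == 0L) .htsqcError("plate has no wells", "emptyPlateError")
  if (mode == "residual") {
    if (is.null(fits)) {
      qc <- plateQC(plate, returnFits = TRUE)
      fits <- attr(qc, "fits")
    }
    if (is.null(fits) || length(fits) == 0L) {
      .htsqcError("residual mode requires per-series fits", "preconditionError")
    }
    series <- extractDoseSeries(plate)
    w$value <- NA_real_
    for (id in names(fits)) {
      f <- fits[[id]]
      p <- seriesPoints(series[[id]])
      k <- scalingFactor(f@fitted / 100)
      idx <- match(paste(p$row, p$col), paste(w$row, w$col))
      w$value[idx] <- abs(f@residuals * k)
    }
    lab <- "|residual x k| (%)"
    pal <- c("white", "#fee8c8", "#e34a33", "#7f0000")
  } else {
    w$value <- w$response
    lab <- "inhibition (%)"
    pal <- c("#2166ac", "white", "#b2182b")
  }
  dims <- plateDim(plate)
  ctrl <- w[w$wellType %in% c("pos_ctrl", "neg_ctrl"), , drop = FALSE]
  gg <- ggplot2::ggplot(w, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_tile(
      data = ctrl, fill = NA, color = "black", linewidth = 0.6
    ) +
    ggplot2::scale_y_reverse(breaks = seq_len(dims[1]), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(breaks = seq_len(dims[2]), expand = c(0, 0)) +
    ggplot2::scale_fill_gradientn(colours = pal, na.value = "grey90", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Plate %s (%s)", plateId(plate), mode),
      x = "column", y = "row"
    ) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 7, height = 4.2, dpi = 150)
    return(invisible(file))
  }
  gg
}

#' Row-wise response distribution plot
#'
#' Boxplots of compound-well responses per plate row; systematic
#' row-level shifts (e.g. gradients, row striping) show up as trends
#' across rows.
#'
#' @param plate a [PlateData-class].
#' @param file optional output path.
#' @return a ggplot object (or the file path).
#' @export
renderRowDistribution <- function(plate, file = NULL) {
  stopifnot(is(plate, "PlateData"))
  w <- wellData(plate)
  w <- w[w$wellType == "compound", , drop = FALSE]
  if (nrow(w) == 0L) .htsqcError("plate has no compound wells", "emptyPlateError")
  gg <- ggplot2::ggplot(w, ggplot2::aes(x = factor(.data$row), y = .data$response)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(
      title = sprintf("Plate %s: row-wise response distribution", plateId(plate)),
      x = "row", y = "inhibition (%)"
    ) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 6, height = 3.5, dpi = 150)
    return(invisible(file))
  }
  gg
}

#' Assemble a QC summary table over plates
#'
#' @param qcResults list of [PlateQCResult-class].
#' @return data.frame with one row per plate: plate_id, nrfe, z_prime,
#'   robust_z_prime, ssmd, s_b, tier, n_series_used, n_series_excluded.
#' @export
qcTable <- function(qcResults) {
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  do.call(rbind, lapply(qcResults, function(q) {
    cm <- controlMetrics(q)
    data.frame(
      plate_id = plateId(q), nrfe = nrfe(q),
      z_prime = num(cm$z_prime), robust_z_prime = num(cm$robust_z_prime),
      ssmd = num(cm$ssmd), s_b = num(cm$s_b),
      tier = qcTier(q),
      n_series_used = q@nSeriesUsed, n_series_excluded = q@nSeriesExcluded,
      stringsAsFactors = FALSE
    )
  }))
}

#' End-to-end QC run over plates
#'
#' Reads (or accepts) plates, computes per-plate QC, writes the QC table
#' (CSV), a JSON report with run configuration and per-plate results,
#' and residual heatmaps for every flagged (borderline or poor) plate.
#' Per-plate failures (e.g. a plate with no fittable series) are caught,
#' logged with a machine-parsable reason code and reported in the bundle
#' rather than aborting the run.
#'
#' @param plates list of [PlateData-class], or a [plateFileSpec()] to
#'   read from.
#' @param outDir output directory (created if needed); NULL disables all
#'   file output.
#' @param thresholds c(borderline, poor) NRFE tier cutoffs.
#' @param weighting,outlierHandling passed to [plateQC()].
#' @param figures write residual heatmaps for flagged plates.
#' @return list of class \code{"ReportBundle"}: \code{table} (the QC
#'   data.frame), \code{results} (list of [PlateQCResult-class]),
#'   \code{failures} (data.frame plate_id / reason), \code{config}
#'   (echo sufficient to re-run), \code{exitStatus} (0 all acceptable,
#'   3 borderline present, 4 poor present).
#' @export
qcRun <- function(plates, outDir = NULL, thresholds = c(10, 15),
                  weighting = "series", outlierHandling = FALSE,
                  figures = TRUE) {
  if (inherits(plates, "PlateFileSpec")) plates <- readPlates(plates)
  if (is(plates, "PlateData")) plates <- list(plates)
  if (length(plates) == 0L) .htsqcError("no plates to process", "ioError")
  results <- list()
  failures <- data.frame(plate_id = character(), reason = character())
  for (p in plates) {
    r <- tryCatch(
      plateQC(p, thresholds = thresholds, weighting = weighting,
              outlierHandling = outlierHandling, returnFits = figures),
      htsqcError = function(e) e
    )
    if (inherits(r, "error")) {
      failures <- rbind(failures, data.frame(
        plate_id = plateId(p), reason = class(r)[1]
      ))
      message(sprintf("[%s] plate %s skipped: %s", class(r)[1], plateId(p), conditionMessage(r)))
    } else {
      results[[plateId(p)]] <- r
    }
  }
  if (length(results) == 0L) {
    .htsqcError("no plate could be processed", "ioError")
  }
  tab <- qcTable(results)
  tiers <- tab$tier
  exitStatus <- if (any(tiers == "poor")) 4L else if (any(tiers == "borderline")) 3L else 0L
  config <- list(
    thresholds = thresholds, weighting = weighting,
    outlierHandling = outlierHandling,
    version = as.character(utils::packageVersion("htsqc"))
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(outDir, "qc_table.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(config = config, table = tab, failures = failures),
      file.path(outDir, "qc_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (figures) {
      flagged <- tab$plate_id[tab$tier != "acceptable"]
      byId <- stats::setNames(plates, vapply(plates, plateId, ""))
      for (pid in flagged) {
        renderPlateHeatmap(
          byId[[pid]], mode = "residual", fits = attr(results[[pid]], "fits"),
          file = file.path(outDir, sprintf("residual_heatmap_%s.png", pid))
        )
      }
    }
  }
  structure(
    list(
      table = tab, results = results, failures = failures,
      config = config, exitStatus = exitStatus
    ),
    class = "ReportBundle"
  )
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat(sprintf(
    "ReportBundle: %d plate(s) processed, %d failed\n  tiers: %s\n  exit status: %d\n",
    nrow(x$table), nrow(x$failures),
    paste(sprintf("%s=%d", names(table(x$table$tier)), table(x$table$tier)), collapse = ", "),
    x$exitStatus
  ))
  invisible(x)
}
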