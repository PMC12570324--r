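#' Describe a long-format plate CSV file
#'
#' The canonical dialect is UTF-8, comma-separated, "." decimal, header
#' required, one row per well. Well positions may be given either as two
#' integer columns (row, col) or as a single label column ("A01" style);
#' set the \code{well} mapping entry for labels, or \code{row}/\code{col}
#' for split coordinates. Responses may be percent inhibition or percent
#' viability (converted on read as 100 - viability); concentrations are
#' converted to micromolar from the declared unit.
#'
#' @param path file path.
#' @param columns named list mapping the logical fields plate, row, col
#'   (or well), compound, concentration, response, well_type to the
#'   file's column names.
#' @param responseKind "inhibition" or "viability".
#' @param concentrationUnit "micromolar", "molar" or "nanomolar".
#' @param geometry plate geometry for coordinate validation (96 or 384).
#' @param wellTypeLevels named character vector translating the file's
#'   well_type codes to the internal levels compound / pos_ctrl /
#'   neg_ctrl / empty; defaults to identity.
#' @return list of class \code{"PlateFileSpec"}.
#' @export
plateFileSpec <- function(path,
                          columns = list(
                            plate = "plate_id", row = "row", col = "col",
                            compound = "compound_id",
                            concentration = "concentration_um",
                            response = "response", well_type = "well_type"
                          ),
                          responseKind = c("inhibition", "viability"),
                          concentrationUnit = c("micromolar", "molar", "nanomolar"),
                          geometry = 96,
                          wellTypeLevels = NULL) {
  responseKind <- match.arg(responseKind)
  concentrationUnit <- match.arg(concentrationUnit)
  logical_ <- c("plate", "compound", "concentration", "response", "well_type")
  if (!all(logical_ %in% names(columns))) {
    .htsqcError(
      paste("column mapping must name:", paste(logical_, collapse = ", ")),
      "schemaError"
    )
  }
  if (!("well" %in% names(columns)) && !all(c("row", "col") %in% names(columns))) {
    .htsqcError("column mapping needs either 'well' or both 'row' and 'col'", "schemaError")
  }
  structure(
    list(
      path = path, columns = columns, responseKind = responseKind,
      concentrationUnit = concentrationUnit, geometry = geometry,
      wellTypeLevels = wellTypeLevels
    ),
    class = "PlateFileSpec"
  )
}

.concFactor <- function(unit) {
  switch(unit, micromolar = 1, molar = 1e6, nanomolar = 1e-3)
}

#' Read plates from a long-format CSV file
#'
#' One [PlateData-class] per distinct plate id. Validation is strict and
#' row-addressed: a missing mapped column raises a schema error naming
#' the column; a non-positive concentration on a compound well, or a
#' duplicated (plate, row, col), raises a validation error with the
#' offending file row number. No row is ever dropped silently.
#'
#' @param spec a [plateFileSpec()].
#' @return named list of [PlateData-class].
#' @export
readPlates <- function(spec) {
  stopifnot(inherits(spec, "PlateFileSpec"))
  if (!file.exists(spec$path)) {
    .htsqcError(sprintf("file not found: %s", spec$path), "ioError")
  }
  df <- utils::read.csv(spec$path, stringsAsFactors = FALSE, check.names = FALSE)
  cm <- spec$columns
  needed <- unlist(cm[names(cm) %in% c("plate", "row", "col", "well", "compound",
                                       "concentration", "response", "well_type")])
  missing_ <- setdiff(needed, names(df))
  if (length(missing_)) {
    .htsqcError(
      sprintf("missing column(s) in %s: %s", spec$path, paste(missing_, collapse = ", ")),
      "schemaError"
    )
  }
  if ("well" %in% names(cm)) {
    coords <- wellLabelToCoords(df[[cm$well]])
  } else {
    coords <- data.frame(row = as.integer(df[[cm$row]]), col = as.integer(df[[cm$col]]))
  }
  dims <- plateGeometry(spec$geometry)
  bad <- which(coords$row < 1L | coords$row > dims[1] | coords$col < 1L | coords$col > dims[2])
  if (length(bad)) {
    .htsqcError(
      sprintf(
        "row %d: well position (%d, %d) outside %d-well geometry",
        bad[1] + 1L, coords$row[bad[1]], coords$col[bad[1]], spec$geometry
      ),
      "validationError"
    )
  }
  wellType <- as.character(df[[cm$well_type]])
  if (!is.null(spec$wellTypeLevels)) {
    mapped <- spec$wellTypeLevels[wellType]
    wellType <- ifelse(is.na(mapped), wellType, unname(mapped))
  }
  unknown <- setdiff(unique(wellType), .WELL_TYPES)
  if (length(unknown)) {
    .htsqcError(
      sprintf("unknown well_type value(s): %s", paste(unknown, collapse = ", ")),
      "validationError"
    )
  }
  response <- as.numeric(df[[cm$response]])
  if (spec$responseKind == "viability") response <- 100 - response
  conc <- as.numeric(df[[cm$concentration]]) * .concFactor(spec$concentrationUnit)
  compound <- as.character(df[[cm$compound]])
  compound[compound == "" | wellType != "compound"] <- NA
  conc[wellType != "compound"] <- NA
  badConc <- which(wellType == "compound" & (!is.finite(conc) | conc <= 0))
  if (length(badConc)) {
    .htsqcError(
      sprintf("row %d: compound well with non-positive or missing concentration", badConc[1] + 1L),
      "validationError"
    )
  }
  plateIds <- as.character(df[[cm$plate]])
  dupKey <- paste(plateIds, coords$row, coords$col)
  if (anyDuplicated(dupKey)) {
    d <- which(duplicated(dupKey))[1]
    .htsqcError(
      sprintf("row %d: duplicated well (%s, %d, %d)", d + 1L, plateIds[d], coords$row[d], coords$col[d]),
      "validationError"
    )
  }
  out <- lapply(unique(plateIds), function(pid) {
    i <- plateIds == pid
    PlateData(
      plateId = pid,
      wells = data.frame(
        row = coords$row[i], col = coords$col[i], wellType = wellType[i],
        compoundId = compound[i], concentration = conc[i], response = response[i],
        stringsAsFactors = FALSE
      ),
      nRows = dims[1], nCols = dims[2]
    )
  })
  names(out) <- unique(plateIds)
  out
}

#' Write plates to the canonical long-format CSV
#'
#' Columns: plate_id, row, col, well_type, compound_id,
#' concentration_um, response. Absent compound ids and concentrations on
#' control wells are written as empty fields (never the string "NA");
#' numeric values round-trip at full precision, so
#' \code{readPlates(writePlates(x))} reproduces \code{x} exactly.
#'
#' @param plates non-empty list of [PlateData-class] (or a single plate).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePlates <- function(plates, path) {
  if (is(plates, "PlateData")) plates <- list(plates)
  if (length(plates) == 0L) {
    .htsqcError("no plates to write", "contractViolation")
  }
  rows <- lapply(plates, function(p) {
    w <- wellData(p)
    data.frame(
      plate_id = plateId(p), row = w$row, col = w$col,
      well_type = w$wellType, compound_id = w$compoundId,
      concentration_um = w$concentration, response = w$response,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  df$concentration_um <- num(df$concentration_um)
  df$response <- num(df$response)
  df$compound_id[is.na(df$compound_id)] <- ""
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e) {
    .htsqcError(sprintf("cannot open '%s' for writing", path), "ioError")
  })
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import DepMap/PharmacoDB-style tabular exports
#'
#' Best-effort adapter for the public GDSC- and PRISM-style long-format
#' exports, maintained against frozen synthetic fixture files shipped
#' with the package (see \code{inst/extdata/synthetic_gdsc_export.csv}),
#' not against live portal schemas. Expected columns (overridable via
#' \code{columns}):
#' \itemize{
#'   \item gdsc: SCAN_ID, POSITION (1-based, row-major), DRUG_ID, CONC
#'     (micromolar), INHIBITION, TAG (DRUG / NC / PC).
#'   \item prism: barcode, row_name (letter), col_name, broad_id, dose
#'     (micromolar), inhibition, well_type (treatment / negcon / poscon).
#' }
#' Rows lacking plate or position information are rejected and counted;
#' the count is attached as attribute \code{"nRejected"} and reported via
#' a message.
#'
#' @param path file path.
#' @param dataset "gdsc" or "prism".
#' @param geometry plate geometry of the export (default 384).
#' @param concentrationUnit unit of the concentration column (default
#'   micromolar; molar values in some raw exports convert by 1e6).
#' @param columns optional named overrides of the column mapping.
#' @return named list of [PlateData-class] with attribute
#'   \code{"nRejected"}.
#' @export
importDepmapStyle <- function(path, dataset = c("gdsc", "prism"),
                              geometry = 384,
                              concentrationUnit = c("micromolar", "molar", "nanomolar"),
                              columns = list()) {
  dataset <- match.arg(dataset)
  concentrationUnit <- match.arg(concentrationUnit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- switch(dataset,
    gdsc = list(
      plate = "SCAN_ID", position = "POSITION", compound = "DRUG_ID",
      concentration = "CONC", response = "INHIBITION", tag = "TAG",
      tagMap = c(DRUG = "compound", NC = "neg_ctrl", PC = "pos_ctrl", EMPTY = "empty")
    ),
    prism = list(
      plate = "barcode", rowName = "row_name", colName = "col_name",
      compound = "broad_id", concentration = "dose", response = "inhibition",
      tag = "well_type",
      tagMap = c(treatment = "compound", negcon = "neg_ctrl", poscon = "pos_ctrl", empty = "empty")
    )
  )
  cm <- utils::modifyList(defaults, columns)
  core <- unlist(cm[names(cm) %in% c("plate", "position", "rowName", "colName",
                                     "compound", "concentration", "response", "tag")])
  missing_ <- setdiff(core, names(df))
  if (length(missing_)) {
    .htsqcError(
      sprintf(
        "unrecognized %s layout: expected column(s) %s; found: %s",
        dataset, paste(missing_, collapse = ", "), paste(names(df), collapse = ", ")
      ),
      "schemaError"
    )
  }
  dims <- plateGeometry(geometry)
  if (dataset == "gdsc") {
    pos <- suppressWarnings(as.integer(df[[cm$position]]))
    row <- (pos - 1L) %/% dims[2] + 1L
    col <- (pos - 1L) %% dims[2] + 1L
  } else {
    row <- suppressWarnings(wellLabelToCoords(
      paste0(df[[cm$rowName]], "1")
    )$row)
    col <- suppressWarnings(as.integer(df[[cm$colName]]))
  }
  plate <- as.character(df[[cm$plate]])
  bad <- is.na(plate) | plate == "" | is.na(row) | is.na(col) |
    row < 1L | row > dims[1] | col < 1L | col > dims[2]
  nRejected <- sum(bad)
  if (nRejected > 0L) {
    message(sprintf("importDepmapStyle: rejected %d row(s) lacking plate/position information", nRejected))
  }
  df <- df[!bad, , drop = FALSE]
  row <- row[!bad]; col <- col[!bad]; plate <- plate[!bad]
  wellType <- unname(cm$tagMap[as.character(df[[cm$tag]])])
  unknown <- is.na(wellType)
  if (any(unknown)) {
    .htsqcError(
      sprintf("unknown well tag value(s): %s", paste(unique(df[[cm$tag]][unknown]), collapse = ", ")),
      "validationError"
    )
  }
  conc <- as.numeric(df[[cm$concentration]]) * .concFactor(concentrationUnit)
  compound <- as.character(df[[cm$compound]])
  compound[wellType != "compound"] <- NA
  conc[wellType != "compound"] <- NA
  out <- lapply(unique(plate), function(pid) {
    i <- plate == pid
    PlateData(
      plateId = pid,
      wells = data.frame(
        row = row[i], col = col[i], wellType = wellType[i],
        compoundId = compound[i], concentration = conc[i],
        response = as.numeric(df[[cm$response]])[i],
        stringsAsFactors = FALSE
      ),
      nRows = dims[1], nCols = dims[2]
    )
  })
  names(out) <- unique(plate)
  attr(out, "nRejected") <- nRejected
  out
}

#' Read a structured (YAML) configuration file
#'
#' Used by the command-line interface for column mappings, tier
#' thresholds and simulator settings; any nesting allowed.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) .htsqcError(sprintf("config not found: %s", path), "ioError")
  yaml::read_yaml(path)
}
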