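test_that("write/read round-trips plates exactly", {
  sim <- simulatePlate(plateSimConfig(geometry = 96, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  writePlates(sim$plate, path)
  back <- readPlates(plateFileSpec(path, geometry = 96))
  expect_length(back, 1L)
  expect_equal(wellData(back[[1]]), wellData(sim$plate))
  expect_equal(plateId(back[[1]]), plateId(sim$plate))
  # and the control-well dialect rule: empty fields, not "NA" strings
  raw <- readLines(path)
  expect_false(any(grepl(",NA,", raw, fixed = TRUE)))
})

test_that("several plates in one file come back as separate PlateData", {
  sims <- lapply(1:3, function(s) {
    simulatePlate(plateSimConfig(geometry = 96, seed = s), plateId = paste0("plate-", s))$plate
  })
  path <- withr::local_tempfile(fileext = ".csv")
  writePlates(sims, path)
  back <- readPlates(plateFileSpec(path, geometry = 96))
  expect_setequal(names(back), paste0("plate-", 1:3))
  expect_error(writePlates(list(), path), class = "contractViolation")
})

test_that("viability responses are converted to inhibition on read", {
  df <- data.frame(
    plate_id = "v", row = 1L, col = 1:4,
    well_type = c("neg_ctrl", "neg_ctrl", "compound", "compound"),
    compound_id = c("", "", "A", "A"),
    concentration_um = c("", "", "0.1", "1"),
    response = c(100, 98, 70, 30)  # viability scale
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  plates <- readPlates(plateFileSpec(path, responseKind = "viability"))
  expect_equal(wellData(plates[[1]])$response, c(0, 2, 30, 70))
})

test_that("well labels parse and out-of-geometry labels are rejected", {
  expect_equal(wellLabelToCoords(c("A01", "B1", "H12", "AA3")),
               data.frame(row = c(1L, 2L, 8L, 27L), col = c(1L, 1L, 12L, 3L)))
  expect_equal(coordsToWellLabel(c(1L, 27L), c(1L, 3L)), c("A01", "AA03"))
  expect_error(wellLabelToCoords("1A"), class = "wellLabelError")

  df <- data.frame(
    plate_id = "x", well = c("A01", "Q99"),
    well_type = c("compound", "compound"),
    compound_id = c("A", "A"), concentration_um = c(1, 2), response = c(10, 20)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  spec <- plateFileSpec(path, columns = list(
    plate = "plate_id", well = "well", compound = "compound_id",
    concentration = "concentration_um", response = "response", well_type = "well_type"
  ), geometry = 96)
  expect_error(readPlates(spec), class = "validationError")
})

test_that("schema and validation errors name the offending column or row", {
  df <- data.frame(plate_id = "x", row = 1L, col = 1L,
                   well_type = "compound", compound_id = "A", response = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(readPlates(plateFileSpec(path)), "concentration_um",
               class = "schemaError")

  df2 <- data.frame(
    plate_id = "x", row = c(1L, 1L, 2L), col = c(1L, 2L, 1L),
    well_type = "compound", compound_id = "A",
    concentration_um = c(1, -2, 3), response = c(5, 6, 7)
  )
  write.csv(df2, path, row.names = FALSE, quote = FALSE)
  expect_error(readPlates(plateFileSpec(path)), "row 3", class = "validationError")

  df3 <- df2
  df3$concentration_um <- 1
  df3$col <- c(1L, 1L, 2L)
  write.csv(df3, path, row.names = FALSE, quote = FALSE)
  expect_error(readPlates(plateFileSpec(path)), "duplicated", class = "validationError")
})

test_that("the GDSC-style adapter maps positions, tags and doses", {
  path <- system.file("extdata", "synthetic_gdsc_export.csv", package = "htsqc")
  plates <- importDepmapStyle(path, dataset = "gdsc")
  expect_length(plates, 1L)
  w <- wellData(plates[[1]])
  expect_equal(nrow(w), 11L)
  # POSITION 25 on a 24-column plate is row 2, col 1
  expect_equal(w$row[w$wellType == "pos_ctrl"][1], 2L)
  expect_equal(sum(w$wellType == "compound"), 7L)
  expect_equal(attr(plates, "nRejected"), 0L)
  series <- extractDoseSeries(plates[[1]])
  expect_setequal(names(series), c("D1001", "D1002"))
})

test_that("the PRISM-style adapter parses letter rows and molar conversion works", {
  path <- system.file("extdata", "synthetic_prism_export.csv", package = "htsqc")
  plates <- importDepmapStyle(path, dataset = "prism")
  w <- wellData(plates[[1]])
  expect_equal(sort(unique(w$row[w$wellType == "compound"])), 3L)
  expect_equal(max(w$concentration, na.rm = TRUE), 10)

  molar <- importDepmapStyle(path, dataset = "prism", concentrationUnit = "molar")
  expect_equal(max(wellData(molar[[1]])$concentration, na.rm = TRUE), 10 * 1e6)
})

test_that("the adapter rejects unrecognized layouts and counts dropped rows", {
  df <- read.csv(system.file("extdata", "synthetic_gdsc_export.csv", package = "htsqc"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "POSITION")], path, row.names = FALSE)
  expect_error(importDepmapStyle(path, dataset = "gdsc"), "POSITION",
               class = "schemaError")

  df$POSITION[2] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_message(plates <- importDepmapStyle(path, dataset = "gdsc"), "rejected 1")
  expect_equal(attr(plates, "nRejected"), 1L)
})

test_that("YAML configuration files round-trip nested mappings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "columns:", "  plate: SCAN_ID", "  response: INHIBITION",
    "thresholds:", "  borderline: 8", "  poor: 12"
  ), path)
  cfg <- readConfigFile(path)
  expect_equal(cfg$columns$plate, "SCAN_ID")
  expect_equal(cfg$thresholds$poor, 12)
  expect_error(readConfigFile("no-such-file.yaml"), class = "ioError")
})
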