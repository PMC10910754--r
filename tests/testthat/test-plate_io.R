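# plate_io: CSV reading/writing, plate maps, validation

test_that("minimal fixture round-trips field for field", {
  tab <- make_minimal_table()
  expect_equal(nrow(tab), 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12,
               ignore_attr = TRUE)  # re-read infers its grid from the records
  expect_equal(attr(back, "timepoints"), attr(tab, "timepoints"))
})

test_that("empty table writes a header-only CSV and reads back", {
  tab <- experiment_table(make_minimal_records()[0, ], dose_grid = c(10, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_measurements(path)), 0)
})

test_that("duplicate (plate, well, timepoint) raises an integrity error naming the triple", {
  recs <- make_minimal_records()
  recs$timepoint_h[2] <- 0  # duplicates P1/A01/0
  err <- expect_error(experiment_table(recs, dose_grid = c(10, 100)),
                      class = "ngr_integrity_error")
  expect_match(conditionMessage(err), "P1/A01/0", fixed = TRUE)
})

test_that("off-grid treated concentration is rejected", {
  recs <- make_minimal_records()
  recs$concentration_nM[recs$well == "A01"] <- default_dose_grid()[1]
  recs$concentration_nM[recs$well == "A02"] <- 17  # display dose, not on the grid
  expect_error(experiment_table(recs, dose_grid = default_dose_grid()),
               class = "ngr_validation_error")
  # the actual third grid dose (17.0998... nM) is accepted
  recs$concentration_nM[recs$well == "A02"] <- default_dose_grid()[3]
  expect_silent(experiment_table(recs, dose_grid = default_dose_grid()))
})

test_that("schema, value and naming violations raise typed errors", {
  recs <- make_minimal_records()
  err <- expect_error(experiment_table(recs[, -match("dead_area", names(recs))]),
                      class = "ngr_schema_error")
  expect_match(conditionMessage(err), "dead_area")

  bad <- recs; bad$total_area[1] <- -5
  expect_error(experiment_table(bad, dose_grid = c(10, 100)),
               class = "ngr_value_error")

  bad <- recs; bad$well[1] <- "Q99"
  expect_error(experiment_table(bad, dose_grid = c(10, 100)),
               class = "ngr_value_error")

  bad <- recs; bad$concentration_nM[1] <- 0  # treated well at 0 is off-grid
  expect_error(experiment_table(bad, dose_grid = c(10, 100)),
               class = "ngr_validation_error")
})

test_that("control wells must carry concentration 0", {
  recs <- make_minimal_records()
  recs$drug <- "vehicle"
  expect_error(experiment_table(recs, dose_grid = c(10, 100)),
               class = "ngr_validation_error")
  recs$concentration_nM <- 0
  expect_silent(experiment_table(recs, dose_grid = c(10, 100)))
})

test_that("a simulated 384-well plate survives a round trip with equal record count", {
  cfg <- default_scenarios()$wt_3d_sensitive
  tab <- simulate_plate(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$total_area, tab$total_area, tolerance = 1e-12)
})

test_that("plate maps annotate raw instrument exports", {
  map <- plate_map(
    wells = data.frame(
      plate_id = "P1",
      wells = c("B02:B05", "A01:A02", "A03:A04"),
      cell_line = "L1",
      drug = c("drugX", "vehicle", "positive_control"),
      role = c("treated", "negative_control", "positive_control"),
      replicate_id = "R1", stringsAsFactors = FALSE),
    dose_grid = c(1, 10, 100, 1000))
  raw <- expand.grid(well = c("B02", "B03", "B04", "B05", "A01", "A02", "A03", "A04"),
                     timepoint_h = c(0, 120), stringsAsFactors = FALSE)
  raw$plate_id <- "P1"; raw$total_area <- 100; raw$dead_area <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE)
  tab <- read_measurements(path, plate_map = map)
  expect_equal(nrow(tab), 16)
  # treated block gets the grid in well order
  b <- as.data.frame(tab)
  b <- b[b$drug == "drugX" & b$timepoint_h == 0, ]
  expect_equal(b$concentration_nM[order(b$well)], c(1, 10, 100, 1000))
  expect_setequal(unique(tab$drug), c("drugX", "vehicle", "positive_control"))
})

test_that("wells missing from the plate map are reported, not dropped", {
  map <- plate_map(
    wells = data.frame(plate_id = "P1", wells = "A01:A04", cell_line = "L1",
                       drug = "drugX", role = "treated", replicate_id = "R1",
                       stringsAsFactors = FALSE),
    dose_grid = c(1, 10, 100, 1000))
  raw <- data.frame(plate_id = "P1", well = c("A01", "Z1", "C09"),
                    timepoint_h = 0, total_area = 1, dead_area = 0,
                    stringsAsFactors = FALSE)
  raw$well <- c("A01", "A05", "C09")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path, row.names = FALSE)
  err <- expect_error(read_measurements(path, plate_map = map),
                      class = "ngr_validation_error")
  expect_match(conditionMessage(err), "A05")
  expect_match(conditionMessage(err), "C09")
})

test_that("plate-map files parse and validate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# demo map", "[dose_grid]", "1,10,100,1000", "[wells]",
    "plate_id,wells,cell_line,drug,role,replicate_id",
    "P1,B02:B05,L1,drugX,treated,R1",
    "P1,A01:A02,L1,vehicle,negative_control,R1"), path)
  map <- read_plate_map(path)
  expect_s3_class(map, "plate_map")
  expect_equal(map$dose_grid, c(1, 10, 100, 1000))
  # treated block size must match the grid
  bad <- plate_map(data.frame(plate_id = "P1", wells = "B02:B04", cell_line = "L1",
                              drug = "drugX", role = "treated", replicate_id = "R1",
                              stringsAsFactors = FALSE),
                   dose_grid = c(1, 10, 100, 1000))
  raw <- data.frame(plate_id = "P1", well = "B02", timepoint_h = 0,
                    total_area = 1, dead_area = 0, stringsAsFactors = FALSE)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, p2, row.names = FALSE)
  expect_error(read_measurements(p2, plate_map = bad),
               class = "ngr_validation_error")
})
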