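# Reading, writing and validating long-format well-level measurement tables.
#
# Interchange format: one CSV row per well per timepoint with exact columns
#   plate_id, well, cell_line, drug, concentration_nM, timepoint_h,
#   total_area, dead_area, replicate_id
# Areas are unitless (only ratios matter downstream). Wells follow 384-well
# naming: row letter A-P plus zero-padded 2-digit column ("B07"). The drug
# labels "vehicle" and "positive_control" are reserved for control wells,
# which must carry concentration 0.

MEASUREMENT_COLUMNS <- c(
  "plate_id", "well", "cell_line", "drug", "concentration_nM",
  "timepoint_h", "total_area", "dead_area", "replicate_id"
)

CONTROL_DRUGS <- c("vehicle", "positive_control")

#' Default 7-point logarithmic dose grid
#'
#' Seven log-spaced concentrations spanning 1--5000 nM, the titration used
#' throughout the package's simulated screens.
#'
#' @param c_min,c_max range endpoints in nM.
#' @param n number of doses.
#' @return numeric vector of concentrations (nM), strictly increasing.
#' @export
default_dose_grid <- function(c_min = 1, c_max = 5000, n = 7) {
  10^seq(log10(c_min), log10(c_max), length.out = n)
}

#' Assemble a validated experiment table
#'
#' Bundles well-level records with the declared dose grid and imaging
#' timepoints, enforcing the structural invariants the downstream NGR
#' pipeline relies on: unique (plate, well, timepoint) triples, non-negative
#' areas and concentrations, control wells at concentration 0, and every
#' treated concentration a member of the declared grid.
#'
#' @param records data.frame with columns `plate_id`, `well`, `cell_line`,
#'   `drug`, `concentration_nM`, `timepoint_h`, `total_area`, `dead_area`,
#'   `replicate_id`.
#' @param dose_grid strictly increasing positive concentrations (nM). If
#'   `NULL`, inferred from the treated records.
#' @param timepoints imaging timepoints (h); inferred if `NULL`.
#' @return an object of class `experiment_table` (a data.frame with
#'   `dose_grid` and `timepoints` attributes).
#' @export
experiment_table <- function(records, dose_grid = NULL, timepoints = NULL) {
  if (!is.data.frame(records)) abort_schema("`records` must be a data.frame")
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(records))
  if (length(missing_cols)) {
    abort_schema(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  records <- records[, MEASUREMENT_COLUMNS, drop = FALSE]
  for (col in c("plate_id", "well", "cell_line", "drug", "replicate_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in c("concentration_nM", "timepoint_h", "total_area", "dead_area")) {
    if (nrow(records) && !is.numeric(records[[col]])) {
      abort_schema(sprintf("column `%s` must be numeric", col))
    }
    records[[col]] <- as.numeric(records[[col]])
  }

  if (nrow(records)) {
    bad_well <- !grepl("^[A-P](0[1-9]|1[0-9]|2[0-4])$", records$well)
    if (any(bad_well)) {
      abort_value(sprintf("malformed well name(s): %s",
                          paste(unique(records$well[bad_well]), collapse = ", ")))
    }
    neg_area <- records$total_area < 0 | records$dead_area < 0
    if (any(neg_area)) {
      abort_value(sprintf("negative area in %d row(s), e.g. %s/%s/%g",
                          sum(neg_area),
                          records$plate_id[neg_area][1],
                          records$well[neg_area][1],
                          records$timepoint_h[neg_area][1]))
    }
    if (any(records$concentration_nM < 0)) {
      abort_value("negative concentration_nM")
    }
    if (any(records$timepoint_h < 0)) abort_value("negative timepoint_h")

    key <- paste(records$plate_id, records$well, records$timepoint_h, sep = "/")
    dup <- duplicated(key)
    if (any(dup)) {
      abort_integrity(sprintf("duplicate (plate, well, timepoint) triple(s): %s",
                              paste(unique(key[dup]), collapse = ", ")),
                      duplicates = unique(key[dup]))
    }

    is_control <- records$drug %in% CONTROL_DRUGS
    if (any(is_control & records$concentration_nM != 0)) {
      abort_validation("control wells must carry concentration 0")
    }
  }

  treated_conc <- unique(records$concentration_nM[
    !(records$drug %in% CONTROL_DRUGS)])
  if (is.null(dose_grid)) {
    dose_grid <- sort(treated_conc)
  }
  dose_grid <- as.numeric(dose_grid)
  if (length(dose_grid)) {
    if (any(dose_grid <= 0) || is.unsorted(dose_grid, strictly = TRUE)) {
      abort_validation("dose_grid must be strictly increasing and positive")
    }
    off <- treated_conc[!conc_in_grid(treated_conc, dose_grid)]
    if (length(off)) {
      abort_validation(sprintf(
        "treated concentration(s) not on the declared dose grid: %s nM",
        paste(format(off), collapse = ", ")), off_grid = off)
    }
  }

  if (is.null(timepoints)) timepoints <- sort(unique(records$timepoint_h))
  rownames(records) <- NULL
  structure(records,
            dose_grid = dose_grid,
            timepoints = as.numeric(timepoints),
            class = c("experiment_table", "data.frame"))
}

# membership with relative tolerance; areas and doses are stored linear
conc_in_grid <- function(conc, grid, rtol = 1e-6) {
  if (!length(conc)) return(logical(0))
  vapply(conc, function(cc) {
    any(abs(cc - grid) <= rtol * pmax(abs(grid), 1e-300))
  }, logical(1))
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf("<experiment_table> %d records, %d plate(s), %d dose(s), %d timepoint(s)\n",
              nrow(x), length(unique(x$plate_id)),
              length(attr(x, "dose_grid")), length(attr(x, "timepoints"))))
  NextMethod()
}

#' Read well-level measurements from CSV
#'
#' Reads the long-format measurement table and returns a validated
#' [experiment_table()]. When the CSV carries only raw instrument columns
#' (`plate_id`, `well`, `timepoint_h`, `total_area`, `dead_area`) a plate map
#' is required to annotate each well with cell line, drug, concentration and
#' replicate; wells absent from the map are rejected with a report of the
#' offending wells.
#'
#' @param path CSV file path.
#' @param plate_map optional [plate_map()] object (or path to a plate-map
#'   file) used to annotate and/or validate wells and to declare the dose
#'   grid.
#' @return an `experiment_table`.
#' @export
read_measurements <- function(path, plate_map = NULL) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)

  raw_cols <- c("plate_id", "well", "timepoint_h", "total_area", "dead_area")
  anno_cols <- setdiff(MEASUREMENT_COLUMNS, raw_cols)
  if (!all(anno_cols %in% names(raw))) {
    # raw instrument export: plate map must supply the annotation
    missing_raw <- setdiff(raw_cols, names(raw))
    if (length(missing_raw)) {
      abort_schema(sprintf("missing required column(s): %s",
                           paste(missing_raw, collapse = ", ")))
    }
    if (is.null(plate_map)) {
      abort_schema(sprintf(
        "columns %s absent and no plate map supplied",
        paste(setdiff(anno_cols, names(raw)), collapse = ", ")))
    }
    raw <- annotate_wells(raw[, raw_cols, drop = FALSE], plate_map)
  }
  grid <- if (!is.null(plate_map)) plate_map$dose_grid else NULL
  experiment_table(raw, dose_grid = grid)
}

#' Write well-level measurements to CSV
#'
#' Inverse of [read_measurements()]: `read_measurements(write_measurements(t))`
#' reproduces `t` field for field.
#'
#' @param table an `experiment_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(inherits(table, "experiment_table"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("directory does not exist: %s", dir))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- plate maps ------------------------------------------------------------

#' Construct a plate map
#'
#' A plate map assigns cell line, drug, role and replicate to well ranges and
#' declares the dose grid. Treated blocks are dosed in order: the i-th well
#' of a treated range receives the i-th grid concentration, so a treated
#' range must contain exactly `length(dose_grid)` wells.
#'
#' @param wells data.frame with columns `plate_id`, `wells` (a single well
#'   "B02", a rectangular range "B02:B08", or a comma list), `cell_line`,
#'   `drug`, `role` (one of `treated`, `negative_control`,
#'   `positive_control`) and `replicate_id`.
#' @param dose_grid strictly increasing positive concentrations (nM).
#' @return object of class `plate_map`.
#' @export
plate_map <- function(wells, dose_grid) {
  need <- c("plate_id", "wells", "cell_line", "drug", "role", "replicate_id")
  if (!is.data.frame(wells) || !all(need %in% names(wells))) {
    abort_schema(sprintf("plate map needs columns: %s", paste(need, collapse = ", ")))
  }
  dose_grid <- as.numeric(dose_grid)
  if (length(dose_grid) < 1 || any(dose_grid <= 0) ||
      is.unsorted(dose_grid, strictly = TRUE)) {
    abort_validation("dose_grid must be strictly increasing and positive")
  }
  bad_role <- !wells$role %in% c("treated", "negative_control", "positive_control")
  if (any(bad_role)) {
    abort_validation(sprintf("unknown role(s): %s",
                             paste(unique(wells$role[bad_role]), collapse = ", ")))
  }
  structure(list(wells = wells, dose_grid = dose_grid), class = "plate_map")
}

#' Read a plate map file
#'
#' Plain-text, two-section format:
#' ```
#' [dose_grid]
#' 1,4.14,17.1,70.7,292,1210,5000
#' [wells]
#' plate_id,wells,cell_line,drug,role,replicate_id
#' P1,B02:B08,HCC78_WT,lorlatinib,treated,R1
#' P1,A01:A04,HCC78_WT,vehicle,negative_control,R1
#' ```
#'
#' @param path plate-map file.
#' @return a [plate_map()] object.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gi <- which(lines == "[dose_grid]")
  wi <- which(lines == "[wells]")
  if (length(gi) != 1 || length(wi) != 1 || wi < gi) {
    abort_schema("plate map must contain a [dose_grid] section followed by [wells]")
  }
  grid <- as.numeric(strsplit(paste(lines[(gi + 1):(wi - 1)], collapse = ","),
                              ",")[[1]])
  if (anyNA(grid)) abort_schema("unparseable dose grid")
  wells <- utils::read.csv(text = paste(lines[(wi + 1):length(lines)],
                                        collapse = "\n"),
                           stringsAsFactors = FALSE)
  plate_map(wells, grid)
}

# "B02" -> "B02"; "B02:B08" -> row-major rectangle; "A01,A03" -> list
expand_well_range <- function(spec) {
  parts <- trimws(strsplit(spec, ",")[[1]])
  out <- character(0)
  for (p in parts) {
    if (grepl("^[A-P][0-9]{2}$", p)) {
      out <- c(out, p)
    } else if (grepl("^[A-P][0-9]{2}:[A-P][0-9]{2}$", p)) {
      ends <- strsplit(p, ":")[[1]]
      r1 <- match(substr(ends[1], 1, 1), LETTERS)
      r2 <- match(substr(ends[2], 1, 1), LETTERS)
      c1 <- as.integer(substr(ends[1], 2, 3))
      c2 <- as.integer(substr(ends[2], 2, 3))
      if (r2 < r1 || c2 < c1) abort_validation(sprintf("inverted well range: %s", p))
      for (r in r1:r2) {
        out <- c(out, sprintf("%s%02d", LETTERS[r], c1:c2))
      }
    } else {
      abort_validation(sprintf("malformed well specifier: %s", p))
    }
  }
  out
}

# per-well lookup table from a plate map, with concentrations assigned
# dose-grid-in-order within each treated block
plate_map_wells <- function(map) {
  stopifnot(inherits(map, "plate_map"))
  blocks <- map$wells
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    w <- expand_well_range(blocks$wells[i])
    role <- blocks$role[i]
    if (role == "treated") {
      if (length(w) != length(map$dose_grid)) {
        abort_validation(sprintf(
          "treated block %s has %d wells but the dose grid has %d doses",
          blocks$wells[i], length(w), length(map$dose_grid)))
      }
      conc <- map$dose_grid
      drug <- blocks$drug[i]
    } else {
      conc <- rep(0, length(w))
      drug <- if (role == "negative_control") "vehicle" else "positive_control"
    }
    out[[i]] <- data.frame(
      plate_id = blocks$plate_id[i], well = w, cell_line = blocks$cell_line[i],
      drug = drug, concentration_nM = conc,
      replicate_id = blocks$replicate_id[i], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  key <- paste(tab$plate_id, tab$well)
  if (anyDuplicated(key)) {
    abort_integrity(sprintf("plate map assigns well(s) twice: %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  tab
}

annotate_wells <- function(raw, map) {
  wells <- plate_map_wells(map)
  key_raw <- paste(raw$plate_id, raw$well)
  key_map <- paste(wells$plate_id, wells$well)
  idx <- match(key_raw, key_map)
  if (anyNA(idx)) {
    offenders <- sort(unique(key_raw[is.na(idx)]))
    abort_validation(sprintf("unmapped well(s): %s",
                             paste(offenders, collapse = ", ")),
                     unmapped = offenders)
  }
  cbind(raw,
        wells[idx, c("cell_line", "drug", "concentration_nM", "replicate_id"),
              drop = FALSE])
}
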