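# Viability, fractional growth and the Normalized Growth Rate (NGR).
#
# V        = max(0, total_area - dead_area)          (floored: segmentation
#                                                     noise can invert the
#                                                     subtraction)
# G        = (V(x) - V(0)) / V(0)
# NGR      =  G / GmedNeg          if G > 0
#          = -(G / GmedPos)        if G < 0
#          =  0                    if G = 0
# clipped to [-1, 1].
#
# GmedNeg / GmedPos are per-plate, per-timepoint medians of vehicle and
# positive (staurosporine-like) control growth. The G<0 branch carries an
# explicit minus sign so the anchors hold: growth equal to the negative
# control maps to +1 (untreated-like), growth equal to the positive control
# maps to -1 (complete killing), and G = 0 maps to 0 (complete growth
# inhibition).

#' Well viability from segmented areas
#'
#' Viability is total brightfield area minus dead-cell (green) area, floored
#' at zero.
#'
#' @param total_area,dead_area non-negative areas (same arbitrary units).
#' @return viability, same units. Vectorized.
#' @export
compute_viability <- function(total_area, dead_area) {
  if (any(total_area < 0) || any(dead_area < 0)) abort_value("negative area")
  pmax(0, total_area - dead_area)
}

#' Fractional growth between two viability readings
#'
#' @param v0 baseline viability (> 0).
#' @param vx viability at the later timepoint (>= 0).
#' @return `(vx - v0) / v0`. Vectorized; recycles like arithmetic.
#' @export
compute_growth <- function(v0, vx) {
  if (any(v0 <= 0)) {
    abort_value("degenerate well: baseline viability must be > 0",
                class = "ngr_degenerate_well")
  }
  if (any(vx < 0)) abort_value("viability must be >= 0")
  (vx - v0) / v0
}

#' Summarize control-well growth for one plate and timepoint
#'
#' Computes the median growth of the vehicle (negative) and positive control
#' wells and enforces the plate QC invariants `GmedNeg > 0` and
#' `GmedPos < 0`: controls that fail to separate make NGR meaningless.
#'
#' @param g_neg growth values of vehicle-control wells.
#' @param g_pos growth values of positive-control wells.
#' @param plate_id,timepoint_h optional labels carried into the summary.
#' @return object of class `control_summary` with fields `GmedNeg`,
#'   `GmedPos`, `n_neg`, `n_pos`, `plate_id`, `timepoint_h`.
#' @export
summarize_controls <- function(g_neg, g_pos, plate_id = NA_character_,
                               timepoint_h = NA_real_) {
  if (!length(g_neg) || !length(g_pos)) {
    abort_qc("missing control wells (need >= 1 vehicle and >= 1 positive control)",
             class = "ngr_missing_control_error")
  }
  gmn <- stats::median(g_neg)
  gmp <- stats::median(g_pos)
  if (!(gmn > 0)) {
    abort_qc(sprintf("plate QC failure: GmedNeg = %.4g is not > 0 (plate %s, %s h)",
                     gmn, plate_id, format(timepoint_h)))
  }
  if (!(gmp < 0)) {
    abort_qc(sprintf("plate QC failure: GmedPos = %.4g is not < 0 (plate %s, %s h)",
                     gmp, plate_id, format(timepoint_h)))
  }
  structure(list(GmedNeg = gmn, GmedPos = gmp,
                 n_neg = length(g_neg), n_pos = length(g_pos),
                 plate_id = plate_id, timepoint_h = timepoint_h),
            class = "control_summary")
}

#' Normalized Growth Rate of a treated well
#'
#' Scales drug-treated growth by the matching control median: positive
#' growth against the vehicle control, negative growth (sign-corrected)
#' against the positive control. Output is clipped to `[-1, 1]`.
#'
#' @param g_drug fractional growth of the treated well(s); vectorized.
#' @param controls a [summarize_controls()] result.
#' @param clip clip the result to `[-1, 1]` (default). `clip = FALSE`
#'   returns the raw value, used only for diagnostics and for detecting
#'   proliferative (> 1) responses.
#' @return NGR value(s).
#' @export
compute_ngr <- function(g_drug, controls, clip = TRUE) {
  stopifnot(inherits(controls, "control_summary"))
  ngr <- ifelse(g_drug > 0, g_drug / controls$GmedNeg,
         ifelse(g_drug < 0, -(g_drug / controls$GmedPos), 0))
  if (clip) ngr <- pmin(1, pmax(-1, ngr))
  ngr
}

#' Qualitative response class of an NGR value
#'
#' `normal` (NGR = 1 within tolerance): growth as in the negative control;
#' `cytostatic` (0 <= NGR < 1): growth inhibition up to full arrest;
#' `cytotoxic` (-1 <= NGR < 0): net cell killing;
#' `proliferative` (NGR > 1): growth above the negative control — only
#' observable on unclipped values.
#'
#' @param ngr NGR value(s), clipped or not.
#' @param tol tolerance for the `normal` anchor (default `1e-6`).
#' @return character vector of classes.
#' @export
classify_response <- function(ngr, tol = 1e-6) {
  ifelse(abs(ngr - 1) <= tol, "normal",
  ifelse(ngr > 1, "proliferative",
  ifelse(ngr >= 0, "cytostatic", "cytotoxic")))
}

#' Compute NGR for every treated well of an experiment
#'
#' Orchestrates the per-well pipeline: baseline and endpoint viability,
#' fractional growth, per-plate control medians at the requested timepoint,
#' and the clipped NGR with its response class. Wells with non-positive
#' baseline viability are excluded with a warning (never silently zeroed).
#'
#' @param table an [experiment_table()].
#' @param timepoint_h readout timepoint; default the last imaging timepoint.
#' @return data.frame of class `ngr_table` with one row per treated well:
#'   `plate_id`, `well`, `cell_line`, `drug`, `concentration_nM`,
#'   `replicate_id`, `timepoint_h`, `ngr`, `ngr_unclipped`, `class`.
#' @export
compute_ngr_table <- function(table, timepoint_h = NULL) {
  stopifnot(inherits(table, "experiment_table"))
  tps <- attr(table, "timepoints")
  if (is.null(timepoint_h)) timepoint_h <- max(tps)
  if (!any(abs(tps - timepoint_h) < 1e-9)) {
    abort_validation(sprintf("timepoint %s h not present in the experiment",
                             format(timepoint_h)))
  }
  df <- as.data.frame(table)
  base <- df[df$timepoint_h == min(tps), ]
  endp <- df[abs(df$timepoint_h - timepoint_h) < 1e-9, ]
  key <- function(d) paste(d$plate_id, d$well)
  idx <- match(key(endp), key(base))
  if (anyNA(idx)) {
    abort_integrity("wells present at the readout timepoint but missing at baseline")
  }
  v0 <- compute_viability(base$total_area[idx], base$dead_area[idx])
  vx <- compute_viability(endp$total_area, endp$dead_area)

  degenerate <- v0 <= 0
  if (any(degenerate)) {
    warning(sprintf("excluding %d well(s) with non-positive baseline viability: %s",
                    sum(degenerate),
                    paste(key(endp)[degenerate], collapse = ", ")))
    endp <- endp[!degenerate, ]; v0 <- v0[!degenerate]; vx <- vx[!degenerate]
  }
  g <- compute_growth(v0, vx)

  out <- vector("list", 0L)
  for (pl in unique(endp$plate_id)) {
    sel <- endp$plate_id == pl
    gp <- g[sel]; dp <- endp[sel, ]
    ctrl <- summarize_controls(gp[dp$drug == "vehicle"],
                               gp[dp$drug == "positive_control"],
                               plate_id = pl, timepoint_h = timepoint_h)
    treated <- !(dp$drug %in% CONTROL_DRUGS)
    if (!any(treated)) next
    gt <- gp[treated]; dt <- dp[treated, ]
    ngr_raw <- compute_ngr(gt, ctrl, clip = FALSE)
    ngr <- pmin(1, pmax(-1, ngr_raw))
    out[[length(out) + 1L]] <- data.frame(
      plate_id = dt$plate_id, well = dt$well, cell_line = dt$cell_line,
      drug = dt$drug, concentration_nM = dt$concentration_nM,
      replicate_id = dt$replicate_id, timepoint_h = timepoint_h,
      ngr = ngr, ngr_unclipped = ngr_raw,
      class = classify_response(ngr_raw),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) abort_data("no treated wells in the experiment")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ngr_table", "data.frame")
  res
}
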