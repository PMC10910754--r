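# Seeded synthetic 384-well screens.
#
# The generator inverts the NGR mapping: a ground-truth GR curve r(c) is
# chosen per cell line x drug, and each treated well's noise-free endpoint
# growth is
#   G(c) = r(c) * neg_growth    if r(c) >= 0   (scaled to vehicle growth)
#        = -r(c) * pos_growth   if r(c) <  0   (scaled to the kill control)
# so that pushing the simulated plate back through the NGR pipeline
# reproduces r(c) exactly when noise_cv = 0. Growth between timepoints is
# geometric in (1 + G); dead-cell area rises as viability falls below the
# vehicle-like growth potential, so viability = total - dead matches the
# growth model. Measurement noise is multiplicative lognormal on the two
# observed areas (the physical observables), with the stated CV and unit
# mean.

#' Build a validated simulation configuration
#'
#' @param truth data.frame with one row per cell line x drug:
#'   `cell_line`, `drug`, `GRinf` in `[-1, 1]`, `GEC50` (nM, > 0),
#'   `h_GR` (> 0).
#' @param dose_grid strictly increasing concentrations (nM), length >= 4;
#'   default the 7-point 1--5000 nM logarithmic titration.
#' @param timepoints imaging times (h); default every 24 h up to 120 h.
#' @param neg_growth fractional growth of the vehicle control over the full
#'   horizon (> 0; default +1.0, one doubling in 120 h).
#' @param pos_growth fractional growth of the staurosporine-like positive
#'   control (in (-1, 0); default -0.9, near-complete killing).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on areas (default 0.05).
#' @param wells_per_dose replicate wells per dose within one plate.
#' @param n_replicates biological replicates; each gets its own plate with
#'   its own controls.
#' @param n_neg_wells,n_pos_wells control wells per plate.
#' @param v0 baseline viability area (arbitrary units).
#' @param culture culture-system label (`"2D"` or `"3D"`).
#' @param seed integer RNG seed; same config (incl. seed) gives a
#'   bit-identical table.
#' @param name scenario name (used in plate ids).
#' @param focal_line the scenario's line of interest (defaults to the first
#'   cell line in `truth`); used by reporting helpers.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(truth,
                              dose_grid = default_dose_grid(),
                              timepoints = seq(0, 120, by = 24),
                              neg_growth = 1.0,
                              pos_growth = -0.9,
                              noise_cv = 0.05,
                              wells_per_dose = 2,
                              n_replicates = 3,
                              n_neg_wells = 8,
                              n_pos_wells = 8,
                              v0 = 1000,
                              culture = "3D",
                              seed = 1L,
                              name = "scenario",
                              focal_line = NULL) {
  need <- c("cell_line", "drug", "GRinf", "GEC50", "h_GR")
  if (!is.data.frame(truth) || !all(need %in% names(truth)) || !nrow(truth)) {
    abort_config(sprintf("truth must be a data.frame with columns: %s",
                         paste(need, collapse = ", ")))
  }
  if (any(truth$GRinf < -1 | truth$GRinf > 1)) abort_config("GRinf must lie in [-1, 1]")
  if (any(truth$GEC50 <= 0)) abort_config("GEC50 must be > 0")
  if (any(truth$h_GR <= 0)) abort_config("h_GR must be > 0")
  dose_grid <- as.numeric(dose_grid)
  if (length(dose_grid) < 4 || any(dose_grid <= 0) ||
      is.unsorted(dose_grid, strictly = TRUE)) {
    abort_config("dose_grid must be strictly increasing, positive, length >= 4")
  }
  timepoints <- sort(unique(as.numeric(timepoints)))
  if (length(timepoints) < 2 || timepoints[1] != 0) {
    abort_config("timepoints must include 0 and at least one later time")
  }
  if (!(neg_growth > 0)) abort_config("neg_growth must be > 0")
  if (!(pos_growth < 0 && pos_growth > -1)) {
    abort_config("pos_growth must lie in (-1, 0)")
  }
  if (noise_cv < 0) abort_config("noise_cv must be >= 0")
  if (wells_per_dose < 1 || n_replicates < 1) {
    abort_config("wells_per_dose and n_replicates must be >= 1")
  }
  if (!culture %in% c("2D", "3D")) abort_config("culture must be \"2D\" or \"3D\"")
  n_wells <- length(unique(truth$drug)) * length(dose_grid) * wells_per_dose +
    n_neg_wells + n_pos_wells
  if (n_wells > 384) {
    abort_config(sprintf("layout needs %d wells per plate; 384 available", n_wells))
  }
  if (is.null(focal_line)) focal_line <- truth$cell_line[1]
  if (!focal_line %in% truth$cell_line) abort_config("focal_line not in truth")
  structure(list(truth = truth, dose_grid = dose_grid, timepoints = timepoints,
                 neg_growth = neg_growth, pos_growth = pos_growth,
                 noise_cv = noise_cv, wells_per_dose = wells_per_dose,
                 n_replicates = n_replicates, n_neg_wells = n_neg_wells,
                 n_pos_wells = n_pos_wells, v0 = v0, culture = culture,
                 seed = as.integer(seed), name = name, focal_line = focal_line),
            class = "simulation_config")
}

well_names_384 <- function(n) {
  if (n > 384) abort_config("more than 384 wells requested")
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  sprintf("%s%02d", rows[seq_len(n)], cols[seq_len(n)])
}

#' Simulate a synthetic screen
#'
#' One plate per cell line per biological replicate: `wells_per_dose` wells
#' at each grid dose per drug, plus vehicle and positive-control wells.
#' Deterministic given the config (including its seed).
#'
#' @param config a [simulation_config()].
#' @return an [experiment_table()].
#' @export
simulate_plate <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be a simulation_config")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  tps <- config$timepoints
  horizon <- max(tps)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  lines <- unique(config$truth$cell_line)
  recs <- vector("list", 0L)

  for (cl in lines) {
    truth_cl <- config$truth[config$truth$cell_line == cl, , drop = FALSE]
    drugs <- truth_cl$drug
    for (rep_i in seq_len(config$n_replicates)) {
      rep_id <- sprintf("R%d", rep_i)
      plate_id <- sprintf("%s_%s_%s", config$name, cl, rep_id)
      # well layout: treated blocks per drug, then controls
      layout <- data.frame(
        drug = c(rep(drugs, each = length(config$dose_grid) * config$wells_per_dose),
                 rep("vehicle", config$n_neg_wells),
                 rep("positive_control", config$n_pos_wells)),
        concentration_nM = c(
          rep(rep(config$dose_grid, each = config$wells_per_dose), times = length(drugs)),
          rep(0, config$n_neg_wells + config$n_pos_wells)),
        stringsAsFactors = FALSE)
      layout$well <- well_names_384(nrow(layout))

      # noise-free endpoint growth per well
      g_end <- numeric(nrow(layout))
      for (i in seq_len(nrow(layout))) {
        dr <- layout$drug[i]
        if (dr == "vehicle") {
          g_end[i] <- config$neg_growth
        } else if (dr == "positive_control") {
          g_end[i] <- config$pos_growth
        } else {
          tr <- truth_cl[truth_cl$drug == dr, ]
          r <- gr_model(layout$concentration_nM[i], tr$GRinf, tr$GEC50, tr$h_GR)
          r <- pmin(1, pmax(-1, r))
          g_end[i] <- if (r >= 0) r * config$neg_growth else -r * config$pos_growth
        }
      }

      frac <- tps / horizon
      for (i in seq_len(nrow(layout))) {
        growth_t <- (1 + g_end[i])^frac - 1          # geometric interpolation
        viab <- config$v0 * (1 + growth_t)
        potential <- config$v0 * (1 + config$neg_growth)^frac
        dead <- pmax(0, potential - viab)
        total <- viab + dead
        if (config$noise_cv > 0) {
          total <- total * exp(stats::rnorm(length(tps), 0, sdlog) - sdlog^2 / 2)
          noisy_dead <- dead * exp(stats::rnorm(length(tps), 0, sdlog) - sdlog^2 / 2)
          dead <- noisy_dead
        }
        recs[[length(recs) + 1L]] <- data.frame(
          plate_id = plate_id, well = layout$well[i], cell_line = cl,
          drug = layout$drug[i],
          concentration_nM = layout$concentration_nM[i],
          timepoint_h = tps, total_area = total, dead_area = dead,
          replicate_id = rep_id, stringsAsFactors = FALSE)
      }
    }
  }
  experiment_table(do.call(rbind, recs), dose_grid = config$dose_grid,
                   timepoints = tps)
}

#' Built-in scenario library
#'
#' Four named, seeded configurations echoing the qualitative regimes of a
#' TKI-resistance screen. Every scenario contains a sensitive wild-type
#' reference line ("WT") plus a second line, so the full pipeline
#' (including the comparison stage) runs on any of them:
#'
#' * `wt_3d_sensitive` — spheroid-like screen; the focal WT line responds
#'   cytotoxically at low nM doses.
#' * `g2032r_like_resistant` — solvent-front-mutant-like focal line: weak
#'   maximal effect at high GEC50; its downstream AOC is far below the
#'   sensitive WT's.
#' * `cytostatic_plateau` — lorlatinib-like regime: truth `GRinf = 0`, the
#'   curve floors at complete growth inhibition and never turns cytotoxic.
#' * `2d_attenuated` — monolayer-like screen with shallower, attenuated
#'   responses and 4 biological replicates.
#'
#' @return named list of [simulation_config()] objects.
#' @export
default_scenarios <- function() {
  wt_sensitive <- data.frame(
    cell_line = "WT", drug = c("tki_a", "tki_b"),
    GRinf = c(-0.6, -0.4), GEC50 = c(30, 60), h_GR = c(2, 2),
    stringsAsFactors = FALSE)
  list(
    wt_3d_sensitive = simulation_config(
      truth = rbind(wt_sensitive, data.frame(
        cell_line = "MUT", drug = c("tki_a", "tki_b"),
        GRinf = c(-0.3, -0.2), GEC50 = c(300, 400), h_GR = c(2, 2),
        stringsAsFactors = FALSE)),
      culture = "3D", n_replicates = 3, seed = 101L,
      name = "wt_3d_sensitive", focal_line = "WT"),
    g2032r_like_resistant = simulation_config(
      truth = rbind(wt_sensitive, data.frame(
        cell_line = "G2032R_like", drug = c("tki_a", "tki_b"),
        GRinf = c(-0.05, 0.0), GEC50 = c(1500, 2000), h_GR = c(1.5, 1.5),
        stringsAsFactors = FALSE)),
      culture = "3D", n_replicates = 3, seed = 102L,
      name = "g2032r_like_resistant", focal_line = "G2032R_like"),
    cytostatic_plateau = simulation_config(
      truth = data.frame(
        cell_line = rep(c("WT", "MUT"), each = 2),
        drug = rep(c("tki_a", "tki_b"), 2),
        GRinf = c(0, 0, 0, 0), GEC50 = c(10, 20, 600, 800),
        h_GR = rep(2, 4), stringsAsFactors = FALSE),
      culture = "3D", n_replicates = 3, seed = 103L,
      name = "cytostatic_plateau", focal_line = "WT"),
    `2d_attenuated` = simulation_config(
      truth = data.frame(
        cell_line = rep(c("WT", "MUT"), each = 2),
        drug = rep(c("tki_a", "tki_b"), 2),
        GRinf = c(-0.1, -0.05, 0.2, 0.25),
        GEC50 = c(150, 250, 1200, 1500),
        h_GR = rep(1.5, 4), stringsAsFactors = FALSE),
      culture = "2D", n_replicates = 4, seed = 104L,
      name = "2d_attenuated", focal_line = "WT"))
}
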