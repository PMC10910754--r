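# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no binary fixtures.

# minimal well-formed record set: one treated well + controls needed for QC,
# two timepoints each
make_minimal_records <- function() {
  data.frame(
    plate_id = "P1",
    well = rep(c("A01", "A02"), each = 2),
    cell_line = "HCC78_WT",
    drug = "lorlatinib",
    concentration_nM = rep(c(10, 100), each = 2),
    timepoint_h = rep(c(0, 120), 2),
    total_area = c(100, 180, 100, 150),
    dead_area = c(0, 10, 0, 20),
    replicate_id = "R1",
    stringsAsFactors = FALSE)
}

make_minimal_table <- function() {
  experiment_table(make_minimal_records(), dose_grid = c(10, 100, 1000, 5000))
}

# a complete single-plate experiment with controls, suitable for
# compute_ngr_table; analytic well growths are chosen directly
make_plate_with_controls <- function(g_treated = c(0.5, 0.2, -0.4),
                                     conc = c(10, 100, 1000),
                                     g_neg = c(0.8, 1.0, 1.2),
                                     g_pos = c(-0.85, -0.9, -0.95),
                                     v0 = 1000) {
  wells <- sprintf("A%02d", seq_len(length(g_treated) + length(g_neg) + length(g_pos)))
  g_all <- c(g_treated, g_neg, g_pos)
  drug <- c(rep("drugX", length(g_treated)),
            rep("vehicle", length(g_neg)),
            rep("positive_control", length(g_pos)))
  cc <- c(conc, rep(0, length(g_neg) + length(g_pos)))
  recs <- do.call(rbind, lapply(seq_along(wells), function(i) {
    data.frame(plate_id = "P1", well = wells[i], cell_line = "L1", drug = drug[i],
               concentration_nM = cc[i], timepoint_h = c(0, 120),
               total_area = c(v0, v0 * (1 + max(0, g_all[i])) +
                                v0 * max(0, -g_all[i])),  # placeholder, fixed below
               dead_area = c(0, 0), replicate_id = "R1",
               stringsAsFactors = FALSE)
  }))
  # set viability directly: total = v0*(1+g) + dead with dead = shortfall vs v0
  for (i in seq_along(wells)) {
    viab <- v0 * (1 + g_all[i])
    dead <- max(0, v0 - viab)
    sel <- recs$well == wells[i] & recs$timepoint_h == 120
    recs$total_area[sel] <- viab + dead
    recs$dead_area[sel] <- dead
  }
  experiment_table(recs, dose_grid = sort(unique(conc)))
}

# Monte-Carlo oracle for the Dunnett many-to-one probability
mc_dunnett <- function(q, lambda, df, n = 1e5, seed = 99) {
  set.seed(seed)
  k <- length(lambda)
  z0 <- rnorm(n)
  u <- sqrt(rchisq(n, df) / df)
  maxT <- rep(0, n)
  for (i in seq_len(k)) {
    Ti <- (sqrt(1 - lambda[i]^2) * rnorm(n) + lambda[i] * z0) / u
    maxT <- pmax(maxT, abs(Ti))
  }
  mean(maxT <= q)
}

# replicate-level AOC tables for the statistics layer
make_aoc_metrics <- function(means, sd = 0.05, n = 4, drugs = c("d1", "d2"),
                             culture = "3D") {
  # means: named list genotype -> per-drug mean vector (recycled)
  rows <- list()
  for (g in names(means)) {
    mu <- rep_len(means[[g]], length(drugs))
    for (j in seq_along(drugs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = g, drug = drugs[j], culture = culture,
        replicate_id = sprintf("R%d", seq_len(n)),
        AOC = rnorm(n, mu[j], sd), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
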