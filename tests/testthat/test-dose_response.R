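# dose_response: GR model, fitting, outlier refit, NGR50, AOC

test_that("gr_model limits: c = 0, c = GEC50, c -> Inf", {
  for (gri in c(-1, -0.3, 0, 0.7)) {
    expect_equal(gr_model(0, gri, 50, 2), 1)
    expect_equal(gr_model(50, gri, 50, 2), (1 + gri) / 2)
    expect_equal(gr_model(Inf, gri, 50, 2), gri)
    expect_equal(gr_model(1e12, gri, 50, 2), gri, tolerance = 1e-6)
  }
})

test_that("noise-free points are recovered to 1e-6 relative", {
  grid <- default_dose_grid()
  y <- gr_model(grid, -0.5, 100, 2)
  fit <- fit_gr(data.frame(concentration_nM = grid, ngr = y))
  expect_true(fit$converged)
  expect_equal(fit$GRinf, -0.5, tolerance = 1e-6)
  expect_equal(fit$GEC50, 100, tolerance = 1e-6)
  expect_equal(fit$h_GR, 2, tolerance = 1e-6)
  expect_false(fit$refitted)
  expect_lt(fit$rmse, 1e-8)
})

test_that("drug-inert profiles degenerate gracefully (AOC ~ 0)", {
  grid <- default_dose_grid()
  fit <- fit_gr(data.frame(concentration_nM = grid, ngr = rep(1, 7)))
  expect_lt(aoc(fit), 1e-3)
  expect_lt(fit$rmse, 1e-3)
})

test_that("insufficient data raises a typed error", {
  expect_error(fit_gr(data.frame(concentration_nM = c(1, 10, 100, 1000),
                                 ngr = c(1, 0.9, 0.5, 0))),
               class = "ngr_insufficient_data_error")
  expect_error(fit_gr(data.frame(concentration_nM = rep(c(1, 10), c(3, 3)),
                                 ngr = rep(0.5, 6))),
               class = "ngr_insufficient_data_error")
})

test_that("outlier rule is conjunctive: 2.5x mean AND 0.25 absolute", {
  expect_equal(detect_outliers(c(0.01, 0.02, -0.01, 0.60)),
               c(FALSE, FALSE, FALSE, TRUE))  # mean |r| = 0.16; 0.60 > 0.40 & > 0.25
  expect_equal(detect_outliers(rep(0.3, 4)), rep(FALSE, 4))    # nothing > 2.5x mean
  expect_equal(detect_outliers(c(0, 0, 0, 0.2)), rep(FALSE, 4)) # below abs floor
})

test_that("outlier flags agree with brute-force recomputation", {
  set.seed(11)
  for (i in 1:50) {
    r <- rnorm(sample(5:12, 1), sd = runif(1, 0.01, 0.4))
    flags <- detect_outliers(r)
    expected <- vapply(seq_along(r), function(j) {
      abs(r[j]) > 2.5 * mean(abs(r)) && abs(r[j]) > 0.25
    }, logical(1))
    expect_identical(flags, expected)
  }
})

test_that("a single corrupted point is flagged and the refit restores truth", {
  grid <- default_dose_grid()
  y <- gr_model(grid, -0.8, 50, 2)
  y[7] <- 0.9  # corrupted top dose
  fit <- fit_gr(data.frame(concentration_nM = grid, ngr = y))
  expect_true(fit$refitted)
  expect_identical(which(fit$outlier_flags), 7L)
  expect_equal(fit$GRinf, -0.8, tolerance = 5e-2)
  expect_equal(fit$GEC50, 50, tolerance = 5e-2)
  expect_equal(fit$h_GR, 2, tolerance = 5e-2)
})

test_that("refit is skipped when flagged removal would leave < 4 points", {
  # 5 points, one flagrant outlier -> removal leaves 4, refit allowed;
  # with exactly 4 remaining the boundary holds, so construct 4+1
  conc <- c(1, 10, 100, 1000, 5000)
  y <- gr_model(conc, -0.6, 80, 2)
  y[3] <- y[3] + 5  # enormous residual at one point
  fit <- fit_gr(data.frame(concentration_nM = conc, ngr = y))
  expect_true(fit$refitted || fit$refit_skipped)
  if (fit$refitted) expect_equal(sum(fit$outlier_flags), 1)
})

test_that("NGR50 closed form matches its definition and censors correctly", {
  f <- function(gri, g, h) structure(
    list(GRinf = gri, GEC50 = g, h_GR = h, c_min = 1, c_max = 5000),
    class = "gr_fit")
  expect_equal(ngr50(f(0, 123, 1.7))$value, 123)  # symmetry: halfway point
  expect_true(ngr50(f(0.6, 100, 2))$censored)     # curve never reaches 0.5
  expect_equal(ngr50(f(0.6, 100, 2))$label, "> 5000")
  expect_equal(ngr50(f(-1, 100, 2))$value, 100 * sqrt(1 / 3), tolerance = 1e-12)
  # right-censoring when the solution exceeds c_max:
  # GRinf = 0.45 -> multiplier (0.5/0.05)^(1/1) = 10x GEC50 = 40000 > 5000
  expect_true(ngr50(f(0.45, 4000, 1))$censored)
  expect_equal(ngr50(f(0.45, 4000, 1))$label, "> 5000")
})

test_that("NGR50 closed form agrees with numeric root-finding to 1e-9 relative", {
  set.seed(21)
  for (i in 1:40) {
    gri <- runif(1, -1, 0.45)
    g <- 10^runif(1, 0.5, 3)
    h <- runif(1, 0.5, 5)
    fit <- structure(list(GRinf = gri, GEC50 = g, h_GR = h,
                          c_min = 1, c_max = 1e9), class = "gr_fit")
    n50 <- ngr50(fit)
    if (n50$censored) next
    root <- uniroot(function(cc) gr_model(cc, gri, g, h) - 0.5,
                    lower = 1e-9, upper = 1e12, tol = 1e-13)$root
    expect_equal(n50$value, root, tolerance = 1e-9)
  }
})

test_that("AOC anchors: flat curves at 1, 0, -1 give 0, 0.5, 1", {
  flat <- function(gri) structure(
    list(GRinf = gri, GEC50 = 1e-9, h_GR = 10, c_min = 1, c_max = 5000),
    class = "gr_fit")
  inert <- structure(list(GRinf = 1, GEC50 = 100, h_GR = 2,
                          c_min = 1, c_max = 5000), class = "gr_fit")
  expect_equal(aoc(inert), 0)
  expect_equal(aoc(flat(0)), 0.5, tolerance = 1e-9)
  expect_equal(aoc(flat(-1)), 1, tolerance = 1e-9)
})

test_that("AOC quadrature converges under grid doubling", {
  fit <- structure(list(GRinf = -0.7, GEC50 = 90, h_GR = 1.3,
                        c_min = 1, c_max = 5000), class = "gr_fit")
  expect_lt(abs(aoc(fit, n = 513) - aoc(fit, n = 1025)), 1e-6)
  expect_lt(abs(aoc(fit, n = 1025) - aoc(fit, n = 2049)), 1e-7)
})

test_that("AOC is monotone in potency and maximal effect", {
  base <- list(GRinf = -0.2, GEC50 = 200, h_GR = 2, c_min = 1, c_max = 5000)
  a0 <- aoc(structure(base, class = "gr_fit"))
  for (gri in seq(-1, -0.2, by = 0.2)) {  # more cytotoxic
    b <- base; b$GRinf <- gri
    expect_gte(aoc(structure(b, class = "gr_fit")) + 1e-12, a0)
  }
  prev <- a0
  for (g in c(150, 100, 50, 10)) {        # more potent
    b <- base; b$GEC50 <- g
    cur <- aoc(structure(b, class = "gr_fit"))
    expect_gte(cur + 1e-12, prev)
    prev <- cur
  }
})

test_that("fit_metrics produces one converged row per replicate with diagnostics", {
  cfg <- simulation_config(
    truth = data.frame(cell_line = "A", drug = c("d1", "d2"),
                       GRinf = c(-0.6, 0), GEC50 = c(50, 200), h_GR = c(2, 1.5),
                       stringsAsFactors = FALSE),
    noise_cv = 0.03, n_replicates = 2, seed = 42)
  m <- fit_metrics(compute_ngr_table(simulate_plate(cfg)), culture = "3D")
  expect_equal(nrow(m), 4)  # 2 drugs x 2 replicates
  expect_true(all(m$converged))
  expect_true(all(m$AOC >= 0 & m$AOC <= 1))
  expect_named(attr(m, "fits"))
  s <- summarize_metrics(m)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_replicates, c(2, 2))
})
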