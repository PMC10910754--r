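# GR-equation dose-response fitting and the NGR50 / AOC metrics.
#
#   GR(c) = GRinf + (1 - GRinf) / (1 + (c / GEC50)^h_GR)
#
# GRinf is the response at infinite concentration, GEC50 the concentration
# producing half the maximum possible effect, h_GR the Hill coefficient.
# Fits are per cell line x drug x replicate, by bounded nonlinear least
# squares (L-BFGS-B on GRinf, log10 GEC50, h_GR) from the fixed initial
# guesses (0.1, median tested concentration, 2). After the first
# convergence a single outlier pass runs: points with |residual| above both
# 2.5x the mean absolute residual and 0.25 are dropped and the model is
# refit once on the retained points.

#' The GR dose-response equation
#'
#' @param c concentration (nM), `>= 0`; vectorized. `Inf` is allowed and
#'   returns `GRinf`.
#' @param GRinf response at infinite concentration, in `[-1, 1]`.
#' @param GEC50 half-maximal-effect concentration (nM), `> 0`.
#' @param h_GR Hill coefficient, `> 0`.
#' @return predicted normalized growth rate(s).
#' @export
gr_model <- function(c, GRinf, GEC50, h_GR) {
  stopifnot(GEC50 > 0, h_GR > 0)
  GRinf + (1 - GRinf) / (1 + (c / GEC50)^h_GR)
}

#' Flag outlier residuals
#'
#' A point is an outlier iff its absolute residual exceeds **both** 2.5
#' times the mean absolute residual and the absolute floor 0.25. The two
#' conditions are conjunctive: homogeneous large errors trigger nothing,
#' and small-scale fits cannot lose points to tiny relative excursions.
#'
#' @param residuals signed residuals (observed minus fitted).
#' @param rel_mult multiple of the mean absolute residual (default 2.5).
#' @param abs_floor absolute residual floor (default 0.25).
#' @return logical vector, `TRUE` for outliers.
#' @export
detect_outliers <- function(residuals, rel_mult = 2.5, abs_floor = 0.25) {
  a <- abs(residuals)
  a > rel_mult * mean(a) & a > abs_floor
}

# bounded SSE minimization in (GRinf, log10 GEC50, h): L-BFGS-B from the
# fixed start, then a damped Gauss-Newton polish with the analytic Jacobian
# (quadratic convergence near the optimum; matters for the near-zero-residual
# fits of noise-free synthetic data, where quasi-Newton stalls ~1e-6 away)
gr_optim <- function(conc, ngr, start, lower, upper) {
  sse <- function(p) {
    pred <- p[1] + (1 - p[1]) / (1 + (conc / 10^p[2])^p[3])
    sum((ngr - pred)^2)
  }
  fit <- stats::optim(start, sse, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e2, pgtol = 1e-12))
  polished <- gr_polish(conc, ngr, fit$par, lower, upper)
  if (polished$value <= fit$value) {
    fit$par <- polished$par
    fit$value <- polished$value
  }
  fit
}

gr_polish <- function(conc, ngr, p, lower, upper, max_iter = 30) {
  value <- NULL
  lc <- log(conc)
  for (iter in seq_len(max_iter)) {
    a <- p[1]; L <- p[2]; h <- p[3]
    x <- exp(h * (lc - log(10) * L))           # (c / GEC50)^h
    s <- 1 / (1 + x)
    pred <- a + (1 - a) * s
    r <- ngr - pred
    value <- sum(r^2)
    J <- cbind(1 - s,
               (1 - a) * h * log(10) * x * s^2,
               -(1 - a) * x * (lc - log(10) * L) * s^2)
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(3), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- pmin(upper, pmax(lower, p + as.numeric(step)))
    a2 <- cand[1]; x2 <- exp(cand[3] * (lc - log(10) * cand[2]))
    v2 <- sum((ngr - (a2 + (1 - a2) / (1 + x2)))^2)
    if (!is.finite(v2) || v2 > value) break
    converged_step <- max(abs(cand - p)) < 1e-14
    p <- cand; value <- v2
    if (converged_step) break
  }
  list(par = p, value = value)
}

#' Fit the GR equation to one replicate's NGR points
#'
#' Bounded nonlinear least squares with the fixed initial guesses
#' (`GRinf = 0.1`, `GEC50 =` median tested concentration, `h_GR = 2`) and
#' the bound box `GRinf` in `[-1, 1]`, `GEC50` in `[c_min/10, 10 c_max]`,
#' `h_GR` in `(0, 10]`. One outlier detection-and-refit pass runs after the
#' first convergence; if dropping flagged points would leave fewer than 4,
#' the original fit is kept and marked `refit_skipped`.
#'
#' @param points data.frame with columns `concentration_nM` and `ngr`
#'   (clipped NGR observations for one cell line x drug x replicate).
#' @return object of class `gr_fit`: list with `GRinf`, `GEC50`, `h_GR`,
#'   `residuals`, `outlier_flags`, `refitted`, `refit_skipped`, `rmse`,
#'   `n_points`, `converged`, `c_min`, `c_max`.
#' @export
fit_gr <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("concentration_nM", "ngr") %in% names(points))) {
    abort_schema("`points` needs columns concentration_nM and ngr")
  }
  conc <- as.numeric(points$concentration_nM)
  ngr <- as.numeric(points$ngr)
  ok <- is.finite(conc) & is.finite(ngr) & conc > 0
  conc <- conc[ok]; ngr <- ngr[ok]
  if (length(conc) < 5 || length(unique(conc)) < 3) {
    abort_data(sprintf(
      "insufficient data: need >= 5 points over >= 3 distinct concentrations, got %d over %d",
      length(conc), length(unique(conc))), class = "ngr_insufficient_data_error")
  }
  c_min <- min(conc); c_max <- max(conc)
  start <- c(0.1, log10(stats::median(unique(conc))), 2)
  lower <- c(-1, log10(c_min / 10), 1e-6)
  upper <- c(1, log10(c_max * 10), 10)

  one_fit <- function(cc, yy) {
    f <- gr_optim(cc, yy, start, lower, upper)
    pred <- f$par[1] + (1 - f$par[1]) / (1 + (cc / 10^f$par[2])^f$par[3])
    list(par = f$par, converged = f$convergence == 0, residuals = yy - pred)
  }

  first <- one_fit(conc, ngr)
  flags <- if (first$converged) detect_outliers(first$residuals)
           else rep(FALSE, length(conc))
  refitted <- FALSE; refit_skipped <- FALSE
  final <- first
  keep <- !flags
  if (any(flags)) {
    if (sum(keep) >= 4) {
      final <- one_fit(conc[keep], ngr[keep])
      refitted <- TRUE
    } else {
      refit_skipped <- TRUE
    }
  }
  # residuals reported on all points against the final curve
  pred_all <- final$par[1] +
    (1 - final$par[1]) / (1 + (conc / 10^final$par[2])^final$par[3])
  res_all <- ngr - pred_all
  used <- if (refitted) keep else rep(TRUE, length(conc))
  structure(list(
    GRinf = final$par[1], GEC50 = 10^final$par[2], h_GR = final$par[3],
    concentration_nM = conc, ngr = ngr,
    residuals = res_all, outlier_flags = flags,
    refitted = refitted, refit_skipped = refit_skipped,
    rmse = sqrt(mean(res_all[used]^2)),
    n_points = length(conc),
    converged = final$converged,
    c_min = c_min, c_max = c_max), class = "gr_fit")
}

#' @export
print.gr_fit <- function(x, ...) {
  cat(sprintf(
    "<gr_fit> GRinf = %.4g, GEC50 = %.4g nM, h_GR = %.4g (n = %d, rmse = %.3g%s%s)\n",
    x$GRinf, x$GEC50, x$h_GR, x$n_points, x$rmse,
    if (x$refitted) sprintf(", refit after %d outlier(s)", sum(x$outlier_flags)) else "",
    if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

#' NGR50: concentration at which the fitted response is 0.5
#'
#' Closed form: `GEC50 * (0.5 / (0.5 - GRinf))^(1/h_GR)` when `GRinf < 0.5`.
#' When the curve never reaches 0.5 (`GRinf >= 0.5`) or the solution lies
#' above `c_max`, the value is right-censored.
#'
#' @param fit a `gr_fit`.
#' @param c_max top tested concentration (nM); defaults to the fit's.
#' @return list with `value` (nM, `NA` if censored), `censored` (logical)
#'   and `label` (e.g. `"57.7"` or `"> 5000"`).
#' @export
ngr50 <- function(fit, c_max = fit$c_max) {
  stopifnot(inherits(fit, "gr_fit"))
  if (fit$GRinf >= 0.5) {
    return(list(value = NA_real_, censored = TRUE,
                label = sprintf("> %g", c_max)))
  }
  val <- fit$GEC50 * (0.5 / (0.5 - fit$GRinf))^(1 / fit$h_GR)
  if (val > c_max) {
    list(value = NA_real_, censored = TRUE, label = sprintf("> %g", c_max))
  } else {
    list(value = val, censored = FALSE, label = format(val))
  }
}

#' Normalized area over the fitted curve (AOC)
#'
#' Area between the line `y = 1` and the fitted curve, integrated over
#' log10 concentration across the tested range and normalized by the
#' maximum attainable area (`2 x` the log-range, the curve floor being
#' `-1`). The curve is clipped to `[-1, 1]` inside the integrand, so the
#' result always lies in `[0, 1]`: 0 = drug-inert, 0.5 = full cytostasis
#' everywhere, 1 = complete killing everywhere.
#'
#' @param fit a `gr_fit` (or list with `GRinf`, `GEC50`, `h_GR`).
#' @param c_min,c_max integration range (nM); defaults to the fit's tested
#'   range.
#' @param n number of log-spaced quadrature points (composite trapezoid;
#'   default 513, minimum 256).
#' @return AOC in `[0, 1]`.
#' @export
aoc <- function(fit, c_min = fit$c_min, c_max = fit$c_max, n = 513) {
  stopifnot(c_min > 0, c_max > c_min, n >= 256)
  u <- seq(log10(c_min), log10(c_max), length.out = n)
  y <- gr_model(10^u, fit$GRinf, fit$GEC50, fit$h_GR)
  integrand <- 1 - pmin(1, pmax(-1, y))
  h <- u[2] - u[1]
  area <- h * (sum(integrand) - (integrand[1] + integrand[n]) / 2)
  area / (2 * (log10(c_max) - log10(c_min)))
}

#' Dense fitted curve for plotting
#'
#' @param fit a `gr_fit`.
#' @param n number of points.
#' @return data.frame with `concentration_nM` and `ngr_fit`.
#' @export
gr_curve <- function(fit, n = 200) {
  cc <- 10^seq(log10(fit$c_min), log10(fit$c_max), length.out = n)
  data.frame(concentration_nM = cc,
             ngr_fit = gr_model(cc, fit$GRinf, fit$GEC50, fit$h_GR))
}

#' Fit all replicates of an NGR table and derive response metrics
#'
#' One GR fit per cell line x drug x replicate, then NGR50 and AOC per fit.
#' Fits that fail to converge are reported with diagnostics, never dropped.
#'
#' @param ngr_points an `ngr_table` from [compute_ngr_table()] (or any
#'   data.frame with `cell_line`, `drug`, `replicate_id`,
#'   `concentration_nM`, `ngr`).
#' @param culture culture-system label attached to the metrics
#'   (`"2D"` or `"3D"`).
#' @return data.frame of class `response_metrics`, one row per fit, with
#'   the fits attached as the `fits` attribute (named
#'   `cell_line|drug|replicate_id`).
#' @export
fit_metrics <- function(ngr_points, culture = "3D") {
  need <- c("cell_line", "drug", "replicate_id", "concentration_nM", "ngr")
  if (!all(need %in% names(ngr_points))) {
    abort_schema(sprintf("ngr_points needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!culture %in% c("2D", "3D")) abort_config("culture must be \"2D\" or \"3D\"")
  sp <- split(ngr_points,
              list(ngr_points$cell_line, ngr_points$drug,
                   ngr_points$replicate_id), drop = TRUE, sep = "|")
  rows <- vector("list", length(sp)); fits <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    d <- sp[[i]]
    fit <- fit_gr(d)
    n50 <- ngr50(fit)
    rows[[i]] <- data.frame(
      cell_line = d$cell_line[1], drug = d$drug[1], culture = culture,
      replicate_id = d$replicate_id[1],
      GRinf = fit$GRinf, GEC50_nM = fit$GEC50, h_GR = fit$h_GR,
      NGR50_nM = n50$value, NGR50_label = n50$label,
      AOC = aoc(fit), rmse = fit$rmse,
      n_outliers = sum(fit$outlier_flags),
      refitted = fit$refitted, converged = fit$converged,
      stringsAsFactors = FALSE)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  ord <- order(out$cell_line, out$drug, out$replicate_id)
  out <- out[ord, ]; rownames(out) <- NULL
  names(fits) <- names(sp)
  attr(out, "fits") <- fits[ord]
  class(out) <- c("response_metrics", "data.frame")
  out
}

#' Mean and SD of response metrics across replicates
#'
#' @param metrics a `response_metrics` table.
#' @return data.frame per cell_line x drug x culture with `AOC_mean`,
#'   `AOC_sd`, `NGR50_mean`, `NGR50_sd` (censored NGR50s excluded, count
#'   reported) and `n_replicates`.
#' @export
summarize_metrics <- function(metrics) {
  sp <- split(metrics, list(metrics$cell_line, metrics$drug, metrics$culture),
              drop = TRUE)
  rows <- lapply(sp, function(d) {
    data.frame(
      cell_line = d$cell_line[1], drug = d$drug[1], culture = d$culture[1],
      n_replicates = nrow(d),
      AOC_mean = mean(d$AOC), AOC_sd = stats::sd(d$AOC),
      NGR50_mean = if (any(is.finite(d$NGR50_nM))) mean(d$NGR50_nM, na.rm = TRUE) else NA_real_,
      NGR50_sd = if (sum(is.finite(d$NGR50_nM)) > 1) stats::sd(d$NGR50_nM, na.rm = TRUE) else NA_real_,
      n_ngr50_censored = sum(!is.finite(d$NGR50_nM)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$culture, out$drug, out$cell_line), ]
}
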