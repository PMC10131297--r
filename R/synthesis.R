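#' Species-level summaries of per-series metrics
#'
#' For each species (within each scenario) computes the median and the
#' 2.5/97.5 percentile interval — linear-interpolation percentiles over the
#' replicate series — of the chosen metrics, together with the number of
#' usable (fittable, non-excluded) series.  Summaries based on fewer than
#' three usable series are flagged unreliable.
#'
#' @param results data.frame from [analyze_batch()].
#' @param metrics Character vector of metric column names.
#' @return data.frame with one row per species x scenario and columns
#'   `<metric>_median`, `<metric>_lo`, `<metric>_hi` for each metric,
#'   plus `n_usable` and `reliable`.
#' @export
summarize_species <- function(results,
                              metrics = c("strength", "component_strength",
                                          "pr_density_feedback",
                                          "stationarity")) {
  usable <- results[results$fittable %in% TRUE, , drop = FALSE]
  key <- interaction(usable$abbr, usable$scenario, drop = TRUE)
  pieces <- lapply(split(usable, key), function(d) {
    row <- data.frame(abbr = d$abbr[1], scenario = d$scenario[1],
                      n_usable = nrow(d),
                      reliable = nrow(d) >= 3,
                      stringsAsFactors = FALSE)
    for (mt in metrics) {
      v <- d[[mt]]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        qs <- c(NA_real_, NA_real_, NA_real_)
      } else {
        qs <- quantile(v, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
      }
      row[[paste0(mt, "_median")]] <- qs[1]
      row[[paste0(mt, "_lo")]] <- qs[2]
      row[[paste0(mt, "_hi")]] <- qs[3]
    }
    row
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Bootstrapped Spearman correlation across species
#'
#' Each bootstrap iteration draws one value uniformly inside every
#' species' 95% interval for the x metric and one for the y metric, then
#' computes Spearman's rho (average ranks for ties) across species; the
#' median and 2.5/97.5 percentiles of the `n_boot` rho values are
#' reported.  Iterations in which either draw vector is constant (rho
#' undefined) are redrawn and counted.
#'
#' @param summaries data.frame from [summarize_species()] restricted to
#'   one scenario.
#' @param x_metric,y_metric Metric base names (e.g. `"component_strength"`,
#'   `"strength"`).
#' @param n_boot Number of bootstrap draws.
#' @param rng_seed Seed.
#' @return A list of class `correlation_result`: `x_metric`, `y_metric`,
#'   `rho_median`, `rho_lower`, `rho_upper`, `n_boot`, `n_species`,
#'   `n_redrawn`.
#' @export
bootstrap_spearman <- function(summaries, x_metric, y_metric,
                               n_boot = 10000, rng_seed = 1) {
  xlo <- summaries[[paste0(x_metric, "_lo")]]
  xhi <- summaries[[paste0(x_metric, "_hi")]]
  ylo <- summaries[[paste0(y_metric, "_lo")]]
  yhi <- summaries[[paste0(y_metric, "_hi")]]
  ok <- is.finite(xlo) & is.finite(xhi) & is.finite(ylo) & is.finite(yhi)
  if (sum(ok) < 5) stop("need at least 5 species with finite intervals")
  xlo <- xlo[ok]; xhi <- xhi[ok]; ylo <- ylo[ok]; yhi <- yhi[ok]
  ns <- sum(ok)
  if ((sd(xlo) == 0 && sd(xhi) == 0 && all(xhi == xlo)) ||
      (sd(ylo) == 0 && sd(yhi) == 0 && all(yhi == ylo))) {
    stop("metric intervals are degenerate (all species identical); ",
         "Spearman rho undefined")
  }
  set.seed(rng_seed)
  rhos <- numeric(n_boot)
  n_redrawn <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      x <- runif(ns, xlo, xhi)
      y <- runif(ns, ylo, yhi)
      if (sd(x) > 0 && sd(y) > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 1000 * n_boot) {
        stop("bootstrap draws persistently degenerate")
      }
    }
    rhos[i] <- cor(x, y, method = "spearman")
  }
  qs <- quantile(rhos, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  structure(list(x_metric = x_metric, y_metric = y_metric,
                 rho_median = qs[1], rho_lower = qs[2], rho_upper = qs[3],
                 n_boot = n_boot, n_species = ns, n_redrawn = n_redrawn),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrapped Spearman rho(%s, %s) over %d species: %.3f [%.3f, %.3f]\n",
    x$x_metric, x$y_metric, x$n_species,
    x$rho_median, x$rho_lower, x$rho_upper))
  invisible(x)
}

#' Exponential-plateau fit
#'
#' Nonlinear least squares of y = ymax - (ymax - y0) exp(-k x)
#' (Levenberg-Marquardt, multi-start over data-driven rate guesses).  With
#' flat data the rate and plateau are unidentifiable; the fit is then
#' returned with `converged = FALSE` rather than an arbitrary answer.
#'
#' @param x,y Numeric vectors (at least 4 finite pairs).
#' @return A list of class `plateau_fit`: `y0`, `ymax`, `k_rate`,
#'   `converged`, `rss`, and the fitted `nls` object (or `NULL`).
#' @export
fit_plateau <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("plateau fit needs at least 4 points")
  span <- max(x) - min(x)
  if (span <= 0 || sd(y) == 0) {
    return(structure(list(y0 = mean(y), ymax = mean(y), k_rate = 0,
                          converged = FALSE, rss = sum((y - mean(y))^2),
                          fit = NULL),
                     class = "plateau_fit"))
  }
  dat <- data.frame(x = x, y = y)
  y0_start <- mean(y[x <= quantile(x, 0.2)])
  ymax_start <- mean(y[x >= quantile(x, 0.8)])
  best <- NULL
  for (k_start in c(0.5, 1, 2, 5, 10) / span) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ymax - (ymax - y0) * exp(-k * x), data = dat,
                        start = list(y0 = y0_start, ymax = ymax_start,
                                     k = k_start),
                        lower = c(-Inf, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(y0 = NA_real_, ymax = NA_real_, k_rate = NA_real_,
                          converged = FALSE, rss = NA_real_, fit = NULL),
                     class = "plateau_fit"))
  }
  cf <- coef(best$fit)
  converged <- isTRUE(best$fit$convInfo$isConv) && cf[["k"]] > 1e-10
  structure(list(y0 = cf[["y0"]], ymax = cf[["ymax"]],
                 k_rate = cf[["k"]], converged = converged,
                 rss = best$rss, fit = best$fit),
            class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf(
    "Plateau fit: y0 = %.4g, ymax = %.4g, k = %.4g (%sconverged)\n",
    x$y0, x$ymax, x$k_rate, if (x$converged) "" else "not "))
  invisible(x)
}

#' Scenario-level report tables
#'
#' Aggregates a per-series results table into the study's headline
#' summaries per scenario: median Pr(density feedback) and the detection
#' rate Pr > 0.5 (the false-positive rate when the scenario has no
#' component feedback), bootstrapped Spearman correlations between
#' component and ensemble strength and between ensemble strength and the
#' stationarity index, and an exponential-plateau fit of ensemble on
#' component strength across species medians.
#'
#' @param results Per-series data.frame from [analyze_batch()].
#' @param n_boot Bootstrap draws for the correlations.
#' @param rng_seed Seed for the bootstraps.
#' @return List with `scenario_table` (one row per scenario),
#'   `species_summary`, `correlations` (list by scenario), `plateaus`
#'   (list by scenario).
#' @export
scenario_report <- function(results, n_boot = 10000, rng_seed = 1) {
  summ <- summarize_species(results)
  scens <- unique(results$scenario)
  correlations <- list()
  plateaus <- list()
  rows <- lapply(scens, function(sc) {
    d <- results[results$scenario == sc & results$fittable %in% TRUE, ]
    s <- summ[summ$scenario == sc, ]
    cor_ce <- tryCatch(
      bootstrap_spearman(s, "component_strength", "strength",
                         n_boot = n_boot, rng_seed = rng_seed),
      error = function(e) NULL)
    cor_ss <- tryCatch(
      bootstrap_spearman(s, "stationarity", "strength",
                         n_boot = n_boot, rng_seed = rng_seed + 1),
      error = function(e) NULL)
    pl <- tryCatch(
      fit_plateau(s$component_strength_median, s$strength_median),
      error = function(e) NULL)
    correlations[[sc]] <<- list(component_vs_ensemble = cor_ce,
                                stationarity_vs_ensemble = cor_ss)
    plateaus[[sc]] <<- pl
    data.frame(
      scenario = sc,
      n_series = nrow(d),
      n_excluded = sum(results$scenario == sc) - nrow(d),
      median_pr_feedback = median(d$pr_density_feedback, na.rm = TRUE),
      detection_rate = mean(d$pr_density_feedback > 0.5, na.rm = TRUE),
      median_strength = median(d$strength, na.rm = TRUE),
      strength_iqr_lo = quantile(d$strength, 0.25, na.rm = TRUE,
                                 names = FALSE),
      strength_iqr_hi = quantile(d$strength, 0.75, na.rm = TRUE,
                                 names = FALSE),
      rho_component_ensemble =
        if (is.null(cor_ce)) NA_real_ else cor_ce$rho_median,
      rho_stationarity_ensemble =
        if (is.null(cor_ss)) NA_real_ else cor_ss$rho_median,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(scenario_table = tab, species_summary = summ,
       correlations = correlations, plateaus = plateaus)
}
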