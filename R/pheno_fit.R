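PHENO_MODELS <- c("random_walk", "exponential", "ricker", "gompertz")

#' Per-capita exponential growth rates of a census series
#'
#' r_t = log(N_(t+1) / N_t) for every transition with strictly positive
#' abundance at both endpoints; other transitions are dropped and counted.
#'
#' @param N_t Yearly abundance series.
#' @param min_transitions Minimum usable transitions for a series to be
#'   considered fittable.
#' @return List with `r` (growth rates), `N` (the predictor abundances
#'   N_t for each kept transition), `n_dropped`, and `fittable`.
#' @export
growth_rates <- function(N_t, min_transitions = 30) {
  N_t <- as.numeric(N_t)
  if (length(N_t) < 2) {
    return(list(r = numeric(0), N = numeric(0),
                n_dropped = 0L, fittable = FALSE))
  }
  a <- N_t[-length(N_t)]
  b <- N_t[-1]
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  list(r = log(b[ok] / a[ok]), N = a[ok],
       n_dropped = sum(!ok),
       fittable = sum(ok) >= min_transitions)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1).
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of estimated parameters (including sigma^2).
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-50, 3, 40)  # 106.667
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one phenomenological logistic-growth model
#'
#' Fits r = alpha + beta * x + eps with Gaussian errors by least squares
#' (the maximum-likelihood estimates), where the model determines the mean
#' structure: `random_walk` fixes alpha = beta = 0 (k = 1 counting only
#' sigma^2); `exponential` estimates alpha with beta = 0 (k = 2); `ricker`
#' regresses r on N_t (k = 3); `gompertz` regresses r on log(N_t) (k = 3).
#' The error variance is the ML estimate RSS/n, giving
#' logL = -n/2 (log(2 pi sigma2) + 1).
#'
#' @param r_t Growth rates.
#' @param N_t Predictor abundances (same length as `r_t`).
#' @param model One of `"random_walk"`, `"exponential"`, `"ricker"`,
#'   `"gompertz"`.
#' @return A list of class `pheno_fit`: `model`, `k`, `alpha_hat`,
#'   `beta_hat`, `sigma2_hat`, `logL`, `AICc`, `ok` (FALSE for a
#'   degenerate fit, e.g. a constant predictor).
#' @export
fit_model <- function(r_t, N_t, model = PHENO_MODELS) {
  model <- match.arg(model)
  n <- length(r_t)
  k <- switch(model, random_walk = 1L, exponential = 2L,
              ricker = 3L, gompertz = 3L)
  if (n < k + 2) stop("too few transitions (n = ", n,
                      ") for model ", model)
  alpha <- 0; beta <- 0; ok <- TRUE
  if (model == "random_walk") {
    rss <- sum(r_t^2)
  } else if (model == "exponential") {
    alpha <- mean(r_t)
    rss <- sum((r_t - alpha)^2)
  } else {
    x <- if (model == "ricker") N_t else log(N_t)
    sxx <- sum((x - mean(x))^2)
    if (!is.finite(sxx) || sxx <= 0) {
      ok <- FALSE
      alpha <- NA_real_; beta <- NA_real_; rss <- NA_real_
    } else {
      beta <- sum((x - mean(x)) * (r_t - mean(r_t))) / sxx
      alpha <- mean(r_t) - beta * mean(x)
      rss <- sum((r_t - alpha - beta * x)^2)
    }
  }
  if (ok) {
    sigma2 <- max(rss / n, 1e-300)
    logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
    ic <- aicc(logL, k, n)
  } else {
    sigma2 <- NA_real_; logL <- NA_real_; ic <- NA_real_
  }
  structure(list(model = model, k = k, n = n,
                 alpha_hat = alpha, beta_hat = beta,
                 sigma2_hat = sigma2, logL = logL, AICc = ic, ok = ok),
            class = "pheno_fit")
}

#' Akaike weights from AICc values
#'
#' w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2), with Delta relative to
#' the smallest AICc.  `NA` entries (degenerate fits) receive zero weight
#' and the remaining weights are renormalised.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  w <- rep(0, length(aicc_values))
  ok <- !is.na(aicc_values)
  if (!any(ok)) stop("no valid AICc values")
  d <- aicc_values[ok] - min(aicc_values[ok])
  ew <- exp(-d / 2)
  w[ok] <- ew / sum(ew)
  names(w) <- names(aicc_values)
  w
}

#' Fit all four phenomenological models to a census series
#'
#' @param N_t Yearly abundance series (or an `abundance_series`).
#' @param min_transitions Fittability floor, see [growth_rates()].
#' @return A list of class `pheno_fits`: the four `pheno_fit`s, the AICc
#'   weight vector, `n_transitions`, and the [ensemble_result()].
#' @export
fit_phenomenological <- function(N_t, min_transitions = 30) {
  if (inherits(N_t, "abundance_series")) N_t <- N_t$N
  gr <- growth_rates(N_t, min_transitions)
  if (!gr$fittable) {
    stop("series not fittable: only ", length(gr$r),
         " usable transitions (need ", min_transitions, ")")
  }
  fits <- lapply(PHENO_MODELS, function(mod) fit_model(gr$r, gr$N, mod))
  names(fits) <- PHENO_MODELS
  w <- akaike_weights(vapply(fits, `[[`, numeric(1), "AICc"))
  if (any(!vapply(fits, `[[`, logical(1), "ok"))) {
    warning("degenerate fit(s) excluded from weight mass")
  }
  structure(list(fits = fits, weights = w,
                 n_transitions = length(gr$r),
                 ensemble = ensemble_result(fits, w)),
            class = "pheno_fits")
}

#' Ensemble density-feedback evidence and strength
#'
#' Pr(density feedback) is the summed AICc weight of the two feedback
#' models (Ricker + Gompertz); the feedback strength is the negated
#' Gompertz slope (positive under compensation, negative under
#' depensation).  The Ricker slope is reported but is not the headline
#' strength because only the Gompertz form captures the multiplicative
#' nature of demographic rates.
#'
#' @param fits Named list of the four `pheno_fit`s.
#' @param weights Weights from [akaike_weights()] (recomputed if omitted).
#' @return List with `pr_density_feedback`, `strength`, `ricker_beta`,
#'   `n_transitions`.
#' @export
ensemble_result <- function(fits, weights = NULL) {
  if (is.null(weights)) {
    weights <- akaike_weights(vapply(fits, `[[`, numeric(1), "AICc"))
  }
  list(pr_density_feedback =
         unname(weights["ricker"] + weights["gompertz"]),
       strength = -fits$gompertz$beta_hat,
       ricker_beta = fits$ricker$beta_hat,
       n_transitions = fits$gompertz$n)
}

#' @export
print.pheno_fits <- function(x, ...) {
  cat("Phenomenological model comparison over", x$n_transitions,
      "transitions:\n")
  for (mod in PHENO_MODELS) {
    f <- x$fits[[mod]]
    cat(sprintf("  %-12s k=%d  AICc=%9.3f  wAICc=%.4f  beta=%+.5g\n",
                mod, f$k, f$AICc, x$weights[[mod]], f$beta_hat))
  }
  cat(sprintf("  Pr(density feedback) = %.4f, strength (-beta_Gompertz) = %+.5g\n",
              x$ensemble$pr_density_feedback, x$ensemble$strength))
  invisible(x)
}

#' Analyse one abundance series end to end
#'
#' Fits the four phenomenological models and computes the component
#' strength and the return-time stationarity index, returning a one-row
#' data.frame ready for aggregation.
#'
#' @param series An `abundance_series`, or a numeric census vector.
#' @param min_transitions Fittability floor.
#' @return One-row data.frame (`NA`-filled for unfittable series, with
#'   `fittable = FALSE`).
#' @export
analyze_series <- function(series, min_transitions = 30) {
  if (is.numeric(series)) {
    series <- structure(list(abbr = NA_character_, scenario = NA_character_,
                             replicate = NA_integer_, N = series,
                             s_red = rep(NA_real_, length(series)),
                             extinct_at = NA_integer_),
                        class = "abundance_series")
  }
  base <- data.frame(abbr = series$abbr, scenario = series$scenario,
                     replicate = series$replicate,
                     extinct = !is.na(series$extinct_at),
                     stringsAsFactors = FALSE)
  gr <- growth_rates(series$N, min_transitions)
  if (!gr$fittable) {
    return(cbind(base, data.frame(
      fittable = FALSE, n_transitions = length(gr$r),
      pr_density_feedback = NA_real_, strength = NA_real_,
      ricker_beta = NA_real_, component_strength = NA_real_,
      mean_r = NA_real_, mean_TR = NA_real_, var_TR = NA_real_,
      crossings = NA_integer_, stationarity = NA_real_)))
  }
  pf <- fit_phenomenological(series$N, min_transitions)
  st <- stationarity_index(return_times(series$N))
  comp <- if (all(is.na(series$s_red))) NA_real_ else
    component_strength(series)
  cbind(base, data.frame(
    fittable = TRUE, n_transitions = pf$n_transitions,
    pr_density_feedback = pf$ensemble$pr_density_feedback,
    strength = pf$ensemble$strength,
    ricker_beta = pf$ensemble$ricker_beta,
    component_strength = comp,
    mean_r = mean(gr$r),
    mean_TR = st$mean_TR, var_TR = st$var_TR,
    crossings = st$M,
    stationarity = if (is.finite(st$index)) st$index else NA_real_))
}

#' Analyse a batch of series
#'
#' @param series_list List of `abundance_series` (e.g. from
#'   [run_scenario()]).
#' @param min_transitions Fittability floor.
#' @return data.frame with one row per series.
#' @export
analyze_batch <- function(series_list, min_transitions = 30) {
  do.call(rbind, lapply(series_list, analyze_series,
                        min_transitions = min_transitions))
}

#' Fit the phenomenological models to a user census file
#'
#' Reads a CSV with columns `year,N` (one row per census) and returns the
#' same per-series summary row produced for simulated series.
#'
#' @param path CSV file path, or a data.frame with columns `year` and `N`.
#' @param min_transitions Fittability floor.
#' @return One-row data.frame, plus the full `pheno_fits` as attribute
#'   `"fits"`.
#' @export
fit_census <- function(path, min_transitions = 30) {
  tab <- if (is.data.frame(path)) path else
    read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "N") %in% names(tab))) {
    stop("census input must have columns year,N")
  }
  tab <- tab[order(tab$year), ]
  out <- analyze_series(as.numeric(tab$N), min_transitions)
  if (isTRUE(out$fittable)) {
    attr(out, "fits") <- fit_phenomenological(as.numeric(tab$N),
                                              min_transitions)
  }
  out
}
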