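#' Feedback parameters of the survival-reduction function
#'
#' The component density feedback multiplies the age-specific survival
#' vector by the modifier S_red = a / (1 + (total_n / b)^c): a is the
#' modifier at zero density (1 means no depression at the origin), b the
#' abundance at which the modifier halves (a proxy for where density
#' limitation bites, calibrated so the population is stable at carrying
#' capacity), and c the steepness of the response.  `applies_to` selects
#' whether the modifier acts on survival only (the study's main design), is
#' split between survival and fertility, or is switched off entirely
#' (S_red identically 1, the null-feedback control).
#'
#' @param a Maximum modifier in (0, 1].
#' @param b Half-saturation abundance (> 0).
#' @param c Steepness exponent (> 0).
#' @param applies_to One of `"survival"`, `"survival+fertility"`, `"none"`.
#' @param surv_exponent,fert_exponent Exponents applied to the modifier for
#'   survival and fertility when the feedback is split (see
#'   [split_feedback_with_fertility()]).
#' @return A list of class `feedback_params`.
#' @export
feedback_params <- function(a = 1, b, c = 2,
                            applies_to = c("survival",
                                           "survival+fertility", "none"),
                            surv_exponent = 1, fert_exponent = 0) {
  applies_to <- match.arg(applies_to)
  stopifnot(a > 0, a <= 1, b > 0, c > 0)
  structure(list(a = a, b = b, c = c, applies_to = applies_to,
                 surv_exponent = surv_exponent,
                 fert_exponent = fert_exponent),
            class = "feedback_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat(sprintf(
    "Survival feedback S_red = %.3g / (1 + (n/%.6g)^%.3g), applies to %s\n",
    x$a, x$b, x$c, x$applies_to))
  invisible(x)
}

#' Survival reduction modifier
#'
#' S_red = a / (1 + (total_n / b)^c), a monotonically non-increasing
#' function of total abundance with S_red(0) = a.
#'
#' @param total_n Total abundance (>= 0; vectorised).
#' @param p A [feedback_params()].
#' @return Modifier value(s) in (0, a].
#' @examples
#' p <- feedback_params(a = 1, b = 1000, c = 2)
#' s_red(c(0, 1000, 2000), p)  # 1, 0.5, 0.2
#' @export
s_red <- function(total_n, p) {
  if (any(total_n < 0)) stop("total abundance must be non-negative")
  if (p$applies_to == "none") return(rep(1, length(total_n)))
  p$a / (1 + (total_n / p$b)^p$c)
}

#' Apply the survival feedback to a survival vector
#'
#' Multiplies every element of `S` by the modifier at the current total
#' abundance and clips the result to `[0, 1]`.  With `applies_to = "none"`
#' the vector is returned unchanged.
#'
#' @param S Survival vector.
#' @param total_n Current total abundance.
#' @param p A [feedback_params()].
#' @return Modified survival vector.
#' @export
apply_feedback <- function(S, total_n, p) {
  v <- s_red(total_n, p)^p$surv_exponent
  pmin(pmax(S * v, 0), 1)
}

#' Strength of the component feedback realised in a series
#'
#' The per-series mean of (1 - S_red,t) over the post-burn-in modifier
#' trace: zero when the feedback never bites (or is disabled) and
#' approaching 1 under maximal survival suppression.
#'
#' @param series An `abundance_series` from [project_series()], or a bare
#'   numeric vector of S_red values.
#' @return Scalar in `[0, 1)`.
#' @export
component_strength <- function(series) {
  s <- if (is.list(series)) series$s_red else series
  s <- s[!is.na(s)]
  if (length(s) == 0) stop("empty modifier trace")
  mean(1 - s)
}

#' Split the feedback between survival and fertility
#'
#' Reapportions the calibrated survival-only modifier so that a fraction
#' `split_fraction` of its effect on the population growth rate is carried
#' by fertility instead.  Survival is multiplied by S_red^(1 - phi) and
#' fertility by S_red^(phi * eS/eF), where eS and eF are the summed
#' survival and fertility elasticities of the Leslie matrix; to first order
#' in log S_red the perturbation of log lambda equals that of the
#' survival-only feedback for every phi (an equal-elasticity split).
#'
#' @param p Calibrated survival-only [feedback_params()].
#' @param split_fraction Fraction phi in `[0, 1]` moved onto fertility.
#' @param L The species' `leslie_matrix` (for elasticities).
#' @return A `feedback_params` with `applies_to = "survival+fertility"` and
#'   the two exponents set (`split_fraction` 0 returns `p` unchanged).
#' @export
split_feedback_with_fertility <- function(p, split_fraction, L) {
  if (split_fraction < 0 || split_fraction > 1) {
    stop("split_fraction must lie in [0, 1]")
  }
  if (split_fraction == 0) return(p)
  el <- leslie_elasticities(L)
  p$applies_to <- "survival+fertility"
  p$surv_exponent <- 1 - split_fraction
  p$fert_exponent <- split_fraction * el$survival / el$fertility
  p
}

#' Summed fertility and survival elasticities of a Leslie matrix
#'
#' Elasticities e_ij = (a_ij / lambda) v_i w_j / <v, w> summed over the
#' fertility row and over the survival subdiagonal plus the terminal corner.
#'
#' @param L A `leslie_matrix`.
#' @return List with elements `fertility` and `survival` (summing to 1).
#' @export
leslie_elasticities <- function(L) {
  M <- L$M
  n <- nrow(M)
  sens <- outer(L$v, L$w) / sum(L$v * L$w)
  E <- (M / L$lambda1) * sens
  fert <- sum(E[1, ])
  surv <- sum(E[cbind(2:n, 1:(n - 1))]) + E[n, n]
  list(fertility = fert, survival = surv)
}

#' Calibrate the feedback half-saturation abundance
#'
#' Fixes a = 1 and the steepness c, then solves for b so the long-term mean
#' per-year growth rate r over replicate stochastic projections (survival
#' resampling only, fixed K, no catastrophes) is zero: the population is
#' then stable, on average, at the species' carrying capacity over the
#' 40-generation horizon.  An initial deterministic guess places the
#' equilibrium modifier at the value that brings lambda to 1 exactly at K;
#' bisection on log(b) against the simulated mean r (common random numbers
#' across evaluations, so the objective is deterministic and monotone)
#' refines it.
#'
#' @param lh A `life_history`.
#' @param L Its `leslie_matrix` (built if omitted).
#' @param c_exponent Steepness c of the feedback (fixed, not searched).
#' @param a Maximum modifier (fixed at 1 by default).
#' @param horizon_generations Projection horizon in generations.
#' @param target_mean_r Target mean per-year growth rate (0 = stability).
#' @param tol Convergence tolerance on the mean r.
#' @param n_reps Replicate projections per objective evaluation.
#' @param rng_seed Root seed for the replicate projections.
#' @param control A [project_control()].
#' @return List with `params` (a [feedback_params()]) and `record` (fields
#'   `achieved_mean_r`, `replicates_used`, `iterations`, `converged`).
#' @export
calibrate_feedback <- function(lh, L = NULL, c_exponent = 2, a = 1,
                               horizon_generations = 40,
                               target_mean_r = 0, tol = 0.002,
                               n_reps = 8, rng_seed = 1,
                               control = project_control()) {
  if (is.null(L)) L <- build_leslie(lh)
  q <- max(round(horizon_generations * L$G), round(L$G) + 31)

  # feasibility: even with no depression at all (S_red = a) the population
  # must be able to grow, otherwise mean r = 0 is unreachable.
  lam_max <- .leslie_from_vectors(pmin(a * lh$S, 1), lh$m)$lambda1
  if (lam_max < 1) {
    warning("feedback calibration infeasible for ", lh$species$abbr,
            ": lambda < 1 even at S_red = a")
    return(list(params = feedback_params(a = a, b = lh$K, c = c_exponent),
                record = list(achieved_mean_r = NA_real_,
                              replicates_used = 0L, iterations = 0L,
                              converged = FALSE)))
  }

  # deterministic anchor: modifier u* with lambda(u* S) = 1, placed at K
  f_star <- uniroot(function(u) {
    .leslie_from_vectors(pmin(u * lh$S, 1), lh$m)$lambda1 - 1
  }, c(1e-4, a), tol = 1e-10)$root
  b0 <- lh$K / (a / f_star - 1)^(1 / c_exponent)

  scen <- scenario_preset("i")
  mean_r <- function(log_b) {
    fp <- feedback_params(a = a, b = exp(log_b), c = c_exponent)
    rs <- unlist(lapply(seq_len(n_reps), function(i) {
      project_series(lh, L, fp, scen, n_years = q,
                     rng_seed = derive_seed(rng_seed, 0L, 0L, i),
                     control = control)$r
    }))
    m <- mean(rs, na.rm = TRUE)
    if (!is.finite(m)) m <- -1   # population collapsed: treat as decline
    m - target_mean_r
  }

  # The stochastic correction to the deterministic anchor is small, so the
  # search stays in a narrow bracket around b0 where the objective is
  # monotone (far smaller b collapses the population through its own
  # low-abundance equilibrium and the sign of mean r is no longer
  # informative about the K-scale root).
  f0 <- mean_r(log(b0))
  it <- 1L
  b_hat <- b0
  achieved <- f0 + target_mean_r
  converged <- abs(f0) <= tol
  if (!converged) {
    if (f0 > 0) {
      hi <- log(b0); f_hi <- f0
      lo <- log(b0) - log(2); f_lo <- mean_r(lo); it <- it + 1L
      if (f_lo > 0) {
        lo <- log(b0) - log(4); f_lo <- mean_r(lo); it <- it + 1L
      }
    } else {
      lo <- log(b0); f_lo <- f0
      hi <- log(b0) + log(2); f_hi <- mean_r(hi); it <- it + 1L
      if (f_hi < 0) {
        hi <- log(b0) + log(4); f_hi <- mean_r(hi); it <- it + 1L
      }
    }
    if (f_lo <= 0 && f_hi >= 0) {
      for (k in seq_len(40)) {
        mid <- (lo + hi) / 2
        f_mid <- mean_r(mid)
        it <- it + 1L
        achieved <- f_mid + target_mean_r
        b_hat <- exp(mid)
        if (abs(f_mid) <= tol / 4 || (hi - lo) < 1e-4) {
          converged <- abs(f_mid) <= tol
          break
        }
        if (f_mid > 0) hi <- mid else lo <- mid
      }
    }
  }
  if (!converged) {
    warning("feedback calibration did not converge for ", lh$species$abbr)
  }
  list(params = feedback_params(a = a, b = b_hat, c = c_exponent),
       record = list(achieved_mean_r = achieved,
                     replicates_used = n_reps,
                     iterations = it,
                     converged = converged))
}

#' Persist calibrated feedback parameters as structured text
#'
#' @param calibrations Named list (by species abbreviation) of results from
#'   [calibrate_feedback()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feedback_params <- function(calibrations, path) {
  rows <- vapply(names(calibrations), function(ab) {
    cl <- calibrations[[ab]]
    sprintf("%s,%.17g,%.17g,%.17g,%.17g,%s", ab,
            cl$params$a, cl$params$b, cl$params$c,
            cl$record$achieved_mean_r, cl$record$converged)
  }, character(1))
  writeLines(c("abbr,a,b,c,achieved_mean_r,converged", rows), path)
  invisible(path)
}

#' Read feedback parameters written by [write_feedback_params()]
#'
#' @param path Input file.
#' @return Named list of [feedback_params()].
#' @export
read_feedback_params <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    feedback_params(a = tab$a[i], b = tab$b[i], c = tab$c[i])
  })
  names(out) <- tab$abbr
  out
}
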