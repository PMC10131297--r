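#' Demographic scenario specification
#'
#' A scenario bundles the perturbations applied on top of the base
#' stochastic projection: catastrophic mortality (generationally scaled), a
#' one-off pulse of mortality, sustained proportional harvest, fluctuation
#' or decline of the carrying capacity (through the feedback's b
#' parameter), and whether the component survival feedback is active at
#' all.  Nine presets are available through [scenario_preset()]:
#'
#' * `i`   stochastic survival only, fixed K, no catastrophes
#' * `ii`  as i plus generationally scaled catastrophes
#' * `iii` as ii plus a single 90% mortality pulse at 20 generations
#' * `iv`  as ii plus harvest calibrated to mean r = -0.001
#' * `v`   as ii plus harvest calibrated to mean r = -0.01
#' * `vi`  as ii with K resampled each year (SD 5%)
#' * `vii` as vi with the resampling SD ramping linearly from 5% to 10%
#' * `viii` as vi with the mean K also declining at rate 0.001 per year
#' * `ix`  no component feedback; catastrophe probability raised so the
#'   population is stable on average (the false-positive control)
#'
#' @param id Scenario label.
#' @param catastrophes_on Logical.
#' @param pulse `NULL` or list with `time_generations` and `mortality`.
#' @param harvest_target_r `NULL`, -0.001 or -0.01 (the calibration target).
#' @param harvest_rate The calibrated yearly offtake proportion (set by
#'   [calibrate_harvest()]; 0 until calibrated).
#' @param k_mode One of `"none"`, `"constant_var"`, `"increasing_var"`,
#'   `"declining"`.
#' @param k_sd,k_sd_final,k_decline_rate Fluctuating-K parameters: the
#'   resampling SD (fraction of the mean), the end-of-projection SD for the
#'   increasing-variance mode, and the exponential decline rate per year.
#' @param component_feedback_on Logical; `FALSE` forces S_red = 1.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(id = "custom",
                          catastrophes_on = TRUE,
                          pulse = NULL,
                          harvest_target_r = NULL,
                          harvest_rate = 0,
                          k_mode = c("none", "constant_var",
                                     "increasing_var", "declining"),
                          k_sd = 0.05, k_sd_final = 0.10,
                          k_decline_rate = 0.001,
                          component_feedback_on = TRUE) {
  k_mode <- match.arg(k_mode)
  structure(list(id = id, catastrophes_on = catastrophes_on, pulse = pulse,
                 harvest_target_r = harvest_target_r,
                 harvest_rate = harvest_rate, k_mode = k_mode,
                 k_sd = k_sd, k_sd_final = k_sd_final,
                 k_decline_rate = k_decline_rate,
                 component_feedback_on = component_feedback_on),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
scenario_preset <- function(id = c("i", "ii", "iii", "iv", "v",
                                   "vi", "vii", "viii", "ix")) {
  id <- match.arg(id)
  switch(id,
    i    = scenario_spec("i", catastrophes_on = FALSE),
    ii   = scenario_spec("ii"),
    iii  = scenario_spec("iii",
                         pulse = list(time_generations = 20, mortality = 0.9)),
    iv   = scenario_spec("iv", harvest_target_r = -0.001),
    v    = scenario_spec("v", harvest_target_r = -0.01),
    vi   = scenario_spec("vi", k_mode = "constant_var"),
    vii  = scenario_spec("vii", k_mode = "increasing_var"),
    viii = scenario_spec("viii", k_mode = "declining"),
    ix   = scenario_spec("ix", component_feedback_on = FALSE))
}

#' Catastrophe parameters
#'
#' A catastrophe is a density-independent ~50% mortality event.  Its yearly
#' probability is the per-generation probability scaled by generation
#' length, C = multiplier * p_per_generation / G; once invoked, the year's
#' transition (survival and recruitment) is multiplied by a
#' Beta-distributed severity centred on `severity_mean` with standard
#' deviation `severity_sd` (`severity_sd = 0` applies the mean
#' deterministically, useful for tests).  The multiplier is 1 and the ramp
#' slope 0 except in the null-feedback scenario, where the hazard rises
#' linearly through the projection, C_t = C * (1 + ramp_slope * (t - 1))
#' (capped at 0.995), with the slope calibrated to offset the population's
#' intrinsic growth over the horizon
#' ([calibrate_null_catastrophes()]).
#'
#' @param p_per_generation Probability of catastrophe per generation.
#' @param severity_mean Mean surviving proportion in a catastrophe year.
#' @param severity_sd SD of the Beta-resampled severity.
#' @param multiplier Scalar on the yearly probability.
#' @param ramp_slope Linear increase per year of the yearly probability,
#'   as a fraction of its baseline.
#' @return A list of class `catastrophe_params`.
#' @export
catastrophe_params <- function(p_per_generation = 0.14,
                               severity_mean = 0.5, severity_sd = 0.05,
                               multiplier = 1, ramp_slope = 0) {
  structure(list(p_per_generation = p_per_generation,
                 severity_mean = severity_mean,
                 severity_sd = severity_sd, multiplier = multiplier,
                 ramp_slope = ramp_slope),
            class = "catastrophe_params")
}

#' Projection controls
#'
#' @param sd_survival SD of the Beta resampling of survival, as a fraction
#'   of each S_x.
#' @param sd_fertility SD of the Gaussian resampling of fertility, as a
#'   fraction of each m_x.
#' @param juvenile_sd_multiplier Multiplier on the survival-resampling SD
#'   for pre-maturity age classes (sensitivity option).
#' @param n0_convention Initial-vector convention, see
#'   [initial_population()].
#' @param extinct_threshold Total abundance below which a series is marked
#'   (quasi-)extinct and truncated.
#' @param integerize Round abundances to whole individuals each year
#'   (default keeps continuous expected values).
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation); both consume the same random-number stream and
#'   produce identical series for a given seed.
#' @return A list of class `project_control`.
#' @export
project_control <- function(sd_survival = 0.05, sd_fertility = 0.05,
                            juvenile_sd_multiplier = 1,
                            n0_convention = "simplified",
                            extinct_threshold = 1,
                            integerize = FALSE,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  structure(list(sd_survival = sd_survival, sd_fertility = sd_fertility,
                 juvenile_sd_multiplier = juvenile_sd_multiplier,
                 n0_convention = n0_convention,
                 extinct_threshold = extinct_threshold,
                 integerize = integerize, engine = engine),
            class = "project_control")
}

# Method-of-moments Beta shape parameters for mean p and standard
# deviation sd; infeasible moments (sd^2 >= p(1-p)) are clamped.
beta_shapes <- function(p, sd, warn = TRUE) {
  vmax <- p * (1 - p)
  bad <- sd^2 >= vmax & vmax > 0
  if (any(bad)) {
    if (warn) warning("beta resampling SD clamped for mean(s) near 0/1")
    sd[bad] <- 0.9 * sqrt(vmax[bad])
  }
  r <- vmax / sd^2 - 1
  list(alpha = p * r, beta = (1 - p) * r)
}

#' Resample a survival vector from Beta distributions
#'
#' Each element is drawn from a Beta distribution with mean S_x and
#' standard deviation `sd_fraction * S_x` (method-of-moments shapes);
#' pre-maturity classes may have their SD inflated.  Elements at 0 or 1, or
#' with a zero SD, are returned unchanged.
#'
#' @param S Survival vector, elements in `[0, 1]`.
#' @param sd_fraction SD as a fraction of the mean.
#' @param juvenile_sd_multiplier SD multiplier for juvenile classes.
#' @param juvenile_classes Integer indices (1-based) of juvenile classes.
#' @return Stochastic survival vector of the same length.
#' @export
resample_survival <- function(S, sd_fraction = 0.05,
                              juvenile_sd_multiplier = 1,
                              juvenile_classes = integer(0)) {
  sd <- sd_fraction * S
  if (length(juvenile_classes)) {
    sd[juvenile_classes] <- sd[juvenile_classes] * juvenile_sd_multiplier
  }
  draw <- S > 0 & S < 1 & sd > 0
  out <- S
  if (any(draw)) {
    sh <- beta_shapes(S[draw], sd[draw])
    out[draw] <- rbeta(sum(draw), sh$alpha, sh$beta)
  }
  out
}

#' Resample a fertility vector from truncated Gaussians
#'
#' Gaussian draws with mean m_x and SD `sd_fraction * m_x`, truncated at
#' zero; zero fertilities stay exactly zero.
#'
#' @param m Fertility vector (>= 0).
#' @param sd_fraction SD as a fraction of the mean.
#' @return Stochastic fertility vector.
#' @export
resample_fertility <- function(m, sd_fraction = 0.05) {
  draw <- m > 0 & sd_fraction > 0
  out <- m
  if (any(draw)) {
    out[draw] <- pmax(0, rnorm(sum(draw), m[draw], sd_fraction * m[draw]))
  }
  out
}

#' Apply the yearly catastrophe lottery to a survival vector
#'
#' With probability `multiplier * p_per_generation / G` the year's survival
#' vector is multiplied by a Beta-resampled severity centred on the mean
#' surviving proportion (~0.5, i.e. a ~50% mortality year).  When the
#' year's fertility vector is supplied it is reduced by the same severity:
#' the event kills individuals of every age present during the year,
#' including the cohort recruited that year (whose first-year survival is
#' implicit in the prebreeding fertility row), so an invoked event reduces
#' the whole population by ~(1 - severity).
#'
#' @param S_year The year's survival vector.
#' @param cp A [catastrophe_params()].
#' @param G Generation length in years (> 0).
#' @param m_year Optional fertility vector for the year.
#' @return List with `S` (possibly reduced vector), `m` (if supplied) and
#'   `occurred` (flag).
#' @export
catastrophe_event <- function(S_year, cp = catastrophe_params(), G,
                              m_year = NULL) {
  if (G <= 0) stop("generation length must be positive")
  C <- cp$multiplier * cp$p_per_generation / G
  u <- runif(1)
  sev <- if (cp$severity_sd > 0) {
    sh <- beta_shapes(cp$severity_mean, cp$severity_sd, warn = FALSE)
    rbeta(1, sh$alpha, sh$beta)
  } else cp$severity_mean
  if (u < C) {
    list(S = S_year * sev,
         m = if (is.null(m_year)) NULL else m_year * sev,
         occurred = TRUE)
  } else {
    list(S = S_year, m = m_year, occurred = FALSE)
  }
}

#' One-off pulse mortality
#'
#' @param n Abundance vector.
#' @param mortality Proportion killed across all age classes.
#' @return Reduced abundance vector.
#' @export
pulse_mortality <- function(n, mortality = 0.90) {
  stopifnot(mortality >= 0, mortality <= 1)
  n * (1 - mortality)
}

#' Proportional harvest offtake
#'
#' Removes a constant proportion of every age class, applied after the
#' yearly matrix transition.
#'
#' @param n Abundance vector.
#' @param h Offtake proportion in `[0, 1]`.
#' @return Reduced abundance vector.
#' @export
harvest_offtake <- function(n, h) {
  stopifnot(h >= 0, h <= 1)
  n * (1 - h)
}

#' Year-specific feedback half-saturation under fluctuating K
#'
#' Returns the b parameter used in year `t`: the base value under
#' `"none"`; a Gaussian draw with SD `sd0 * mean` under `"constant_var"`;
#' an SD ramping linearly from `sd0` to `sd1` across the projection under
#' `"increasing_var"`; and a mean decaying as `base_b * exp(-rate * t)`
#' (SD `sd0` of the declining mean) under `"declining"`.  Non-positive
#' draws are redrawn.
#'
#' @param t Year index (1-based).
#' @param base_b Baseline b.
#' @param mode K-fluctuation mode (see [scenario_spec()]).
#' @param q Projection length in years (for the variance ramp).
#' @param sd0,sd1 Fractional SDs.
#' @param rate Exponential decline rate per year.
#' @return A positive scalar.
#' @export
k_schedule <- function(t, base_b,
                       mode = c("none", "constant_var", "increasing_var",
                                "declining"),
                       q = NULL, sd0 = 0.05, sd1 = 0.10, rate = 0.001) {
  mode <- match.arg(mode)
  if (mode == "none") return(base_b)
  mu <- base_b
  sdf <- sd0
  if (mode == "increasing_var") {
    stopifnot(!is.null(q))
    sdf <- sd0 + (sd1 - sd0) * if (q > 1) (t - 1) / (q - 1) else 0
  }
  if (mode == "declining") mu <- base_b * exp(-rate * t)
  repeat {
    b <- rnorm(1, mu, sdf * mu)
    if (b > 0) return(b)
    warning("non-positive K draw redrawn")
  }
}

#' Derive a reproducible sub-seed
#'
#' Deterministically folds a root seed with species, scenario and replicate
#' indices through a multiplicative-congruential chain (modulus 2^31 - 1),
#' so every series in a design has an independent, reconstructible seed.
#'
#' @param base_seed Root integer seed.
#' @param species_idx,scenario_idx,replicate Non-negative integers.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, species_idx = 0L, scenario_idx = 0L,
                        replicate = 0L) {
  m <- 2147483647
  x <- abs(base_seed) %% m
  for (k in c(species_idx, scenario_idx, replicate, 1)) {
    x <- (x * 48271 + k) %% m
  }
  as.integer(max(x, 1))
}

# Assemble the flat argument list shared by the two projection engines.
.projection_args <- function(lh, L, fp, scenario, cp, n_years, control) {
  G <- if (!is.null(L$G)) L$G else generation_length(L)
  q <- if (!is.null(n_years)) n_years else {
    if (!is.null(lh$species$q_yr)) lh$species$q_yr else round(40 * G)
  }
  stopifnot(q > round(G) + 1)
  nage <- lh$omega + 1L
  juv <- if (!is.null(lh$maturity) && lh$maturity >= 1) {
    seq_len(lh$maturity)
  } else integer(0)
  sdS <- control$sd_survival * lh$S
  if (length(juv)) sdS[juv] <- sdS[juv] * control$juvenile_sd_multiplier
  draw_surv <- lh$S > 0 & lh$S < 1 & sdS > 0
  shapes <- list(alpha = rep(1, nage), beta = rep(1, nage))
  if (any(draw_surv)) {
    sh <- beta_shapes(lh$S[draw_surv], sdS[draw_surv], warn = FALSE)
    shapes$alpha[draw_surv] <- sh$alpha
    shapes$beta[draw_surv] <- sh$beta
  }
  m_sd <- ifelse(lh$m > 0, control$sd_fertility * lh$m, 0)
  sev <- beta_shapes(cp$severity_mean, max(cp$severity_sd, 1e-12),
                     warn = FALSE)
  feedback_on <- scenario$component_feedback_on &&
    fp$applies_to != "none"
  cat_prob <- cp$multiplier * cp$p_per_generation / G
  if (scenario$catastrophes_on && cat_prob >= 1) {
    stop("yearly catastrophe probability >= 1")
  }
  pulse_year <- if (!is.null(scenario$pulse)) {
    round(scenario$pulse$time_generations * G)
  } else -1L
  pulse_mort <- if (!is.null(scenario$pulse)) scenario$pulse$mortality else 0
  k_mode <- match(scenario$k_mode,
                  c("none", "constant_var", "increasing_var", "declining")) - 1L
  list(S0 = lh$S, m0 = lh$m,
       beta_a = shapes$alpha, beta_b = shapes$beta, draw_surv = draw_surv,
       m_sd = m_sd,
       n0 = initial_population(lh, L, control$n0_convention),
       q = as.integer(q), G = G, burn_in = as.integer(round(G)),
       feedback_on = feedback_on,
       fb_a = fp$a, fb_b = fp$b, fb_c = fp$c,
       surv_exp = fp$surv_exponent,
       fert_exp = if (fp$applies_to == "survival+fertility")
         fp$fert_exponent else 0,
       cat_on = isTRUE(scenario$catastrophes_on),
       cat_prob = cat_prob, cat_slope = cp$ramp_slope,
       sev_a = sev$alpha, sev_b = sev$beta,
       sev_fixed = cp$severity_sd <= 0, sev_mean = cp$severity_mean,
       k_mode = k_mode, k_sd0 = scenario$k_sd, k_sd1 = scenario$k_sd_final,
       k_decline = scenario$k_decline_rate,
       harvest = scenario$harvest_rate,
       pulse_year = as.integer(pulse_year), pulse_mort = pulse_mort,
       integerize = isTRUE(control$integerize),
       extinct_threshold = control$extinct_threshold)
}

# Reference projection engine in pure R; consumes random numbers in exactly
# the same order as the compiled kernel.
.project_engine_r <- function(a) {
  nage <- length(a$S0)
  n <- a$n0
  Nt <- rep(NA_real_, a$q)
  sred <- rep(NA_real_, a$q)
  extinct_at <- NA_integer_
  for (t in seq_len(a$q)) {
    St <- a$S0
    if (any(a$draw_surv)) {
      St[a$draw_surv] <- rbeta(sum(a$draw_surv),
                               a$beta_a[a$draw_surv],
                               a$beta_b[a$draw_surv])
    }
    mt <- a$m0
    dm <- a$m_sd > 0
    if (any(dm)) mt[dm] <- pmax(0, rnorm(sum(dm), a$m0[dm], a$m_sd[dm]))
    bt <- a$fb_b
    if (a$k_mode > 0) {
      mu <- a$fb_b
      sdf <- a$k_sd0
      if (a$k_mode == 2) {
        sdf <- a$k_sd0 + (a$k_sd1 - a$k_sd0) *
          if (a$q > 1) (t - 1) / (a$q - 1) else 0
      }
      if (a$k_mode == 3) mu <- a$fb_b * exp(-a$k_decline * t)
      repeat {
        bt <- rnorm(1, mu, sdf * mu)
        if (bt > 0) break
      }
    }
    tot <- sum(n)
    v <- 1
    if (a$feedback_on) {
      v <- a$fb_a / (1 + (tot / bt)^a$fb_c)
      St <- pmin(St * v^a$surv_exp, 1)
      if (a$fert_exp > 0) mt <- mt * v^a$fert_exp
    }
    sred[t] <- v
    if (a$cat_on) {
      u <- runif(1)
      sev <- if (a$sev_fixed) a$sev_mean else rbeta(1, a$sev_a, a$sev_b)
      C_t <- min(a$cat_prob * (1 + a$cat_slope * (t - 1)), 0.995)
      if (u < C_t) {
        # the event kills ~(1 - sev) of all individuals present during the
        # year, including the cohort recruited that year
        St <- St * sev
        mt <- mt * sev
      }
    }
    nnew <- numeric(nage)
    nnew[1] <- sum(mt * n)
    if (nage > 1) nnew[2:nage] <- St[1:(nage - 1)] * n[1:(nage - 1)]
    nnew[nage] <- nnew[nage] + St[nage] * n[nage]
    if (t == a$pulse_year) nnew <- nnew * (1 - a$pulse_mort)
    if (a$harvest > 0) nnew <- nnew * (1 - a$harvest)
    if (a$integerize) nnew <- round(nnew)
    n <- nnew
    Nt[t] <- sum(n)
    if (!is.finite(Nt[t]) || Nt[t] < a$extinct_threshold) {
      extinct_at <- t
      break
    }
  }
  list(N = Nt, s_red = sred, extinct_at = extinct_at)
}

#' Project one stochastic abundance time series
#'
#' Runs the yearly projection loop for `n_years` (default: the species'
#' tabulated q, i.e. 40 generations): resample survival (Beta) and
#' fertility (Gaussian), apply the survival feedback at the current total
#' abundance (with the year-specific b under fluctuating K), apply the
#' catastrophe lottery, advance the age vector through the Leslie
#' transition, then apply pulse/harvest mortality and record the total.
#' The first generation (round(G) years) is discarded as burn-in so the
#' deterministic initial age structure can settle into its stochastic
#' quasi-equilibrium.
#'
#' @param lh A `life_history`.
#' @param L Its `leslie_matrix` (built if omitted).
#' @param fp A [feedback_params()].
#' @param scenario A [scenario_spec()] or preset.
#' @param cp A [catastrophe_params()].
#' @param n_years Projection length in years before burn-in removal.
#' @param rng_seed Seed for the series (`NULL` continues the current RNG
#'   stream).
#' @param control A [project_control()].
#' @param replicate Replicate index recorded in the result.
#' @return A list of class `abundance_series`: `N` (post-burn-in yearly
#'   totals), `s_red` (modifier trace), `r` (log growth rates, `NA` across
#'   non-positive endpoints), `extinct_at`, plus bookkeeping fields
#'   (`abbr`, `scenario`, `replicate`, `seed`, `G`, `q`, `burn_in`).
#' @export
project_series <- function(lh, L = NULL, fp,
                           scenario = scenario_preset("i"),
                           cp = catastrophe_params(),
                           n_years = NULL, rng_seed = NULL,
                           control = project_control(),
                           replicate = NA_integer_) {
  if (is.null(L)) L <- build_leslie(lh)
  args <- .projection_args(lh, L, fp, scenario, cp, n_years, control)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  raw <- if (control$engine == "cpp") {
    project_core_cpp(args$S0, args$m0, args$beta_a, args$beta_b,
                     args$draw_surv, args$m_sd, args$n0, args$q,
                     args$feedback_on, args$fb_a, args$fb_b, args$fb_c,
                     args$surv_exp, args$fert_exp,
                     args$cat_on, args$cat_prob, args$cat_slope,
                     args$sev_a, args$sev_b,
                     args$sev_fixed, args$sev_mean,
                     args$k_mode, args$k_sd0, args$k_sd1, args$k_decline,
                     args$harvest, args$pulse_year, args$pulse_mort,
                     args$integerize, args$extinct_threshold)
  } else {
    .project_engine_r(args)
  }
  keep <- seq.int(args$burn_in + 1L, args$q)
  N <- raw$N[keep]
  s_red <- raw$s_red[keep]
  ok <- !is.na(N)
  N <- N[seq_len(max(which(ok), 0))]
  s_red <- s_red[seq_along(N)]
  r <- if (length(N) >= 2) {
    rr <- log(N[-1] / N[-length(N)])
    rr[!is.finite(rr)] <- NA_real_
    rr
  } else numeric(0)
  extinct_at <- raw$extinct_at
  if (length(extinct_at) == 0) extinct_at <- NA_integer_
  structure(list(abbr = lh$species$abbr, scenario = scenario$id,
                 replicate = replicate, seed = rng_seed,
                 N = N, s_red = s_red, r = r,
                 extinct_at = extinct_at,
                 G = args$G, q = args$q, burn_in = args$burn_in),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat(sprintf(
    "Abundance series %s/%s rep %s: %d post-burn-in years, N in [%.4g, %.4g]%s\n",
    x$abbr, x$scenario, x$replicate, length(x$N),
    suppressWarnings(min(x$N, na.rm = TRUE)),
    suppressWarnings(max(x$N, na.rm = TRUE)),
    if (!is.na(x$extinct_at)) paste0(", extinct at year ", x$extinct_at)
    else ""))
  invisible(x)
}

#' Run many replicate series for one scenario
#'
#' @param preps Named list of per-species preparations as returned by
#'   [prepare_species()] (fields `lh`, `L`, `fp`, `cp`, and optionally
#'   per-scenario harvest rates / catastrophe multipliers).
#' @param scenario A [scenario_spec()] or preset id string.
#' @param n_reps Replicates per species.
#' @param base_seed Root seed; per-series seeds come from [derive_seed()].
#' @param control A [project_control()].
#' @return List of `abundance_series` (species-major order).
#' @export
run_scenario <- function(preps, scenario, n_reps, base_seed,
                         control = project_control()) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  scen_idx <- match(scenario$id,
                    c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii",
                      "ix"), nomatch = 0L)
  out <- vector("list", length(preps) * n_reps)
  k <- 0L
  for (si in seq_along(preps)) {
    pr <- preps[[si]]
    scen <- scenario
    if (!is.null(scen$harvest_target_r)) {
      hr <- pr$harvest_rates[[as.character(scen$harvest_target_r)]]
      if (is.null(hr)) stop("harvest rate not calibrated for species ",
                            pr$lh$species$abbr)
      scen$harvest_rate <- hr
    }
    cp <- pr$cp
    if (identical(scen$id, "ix")) {
      if (is.null(pr$null_cat_ramp)) {
        stop("null-feedback catastrophe ramp not calibrated for ",
             pr$lh$species$abbr)
      }
      cp$ramp_slope <- pr$null_cat_ramp
    }
    for (rep_i in seq_len(n_reps)) {
      k <- k + 1L
      out[[k]] <- project_series(
        pr$lh, pr$L, pr$fp, scen, cp,
        rng_seed = derive_seed(base_seed, si, scen_idx, rep_i),
        control = control, replicate = rep_i)
    }
  }
  out
}

#' Calibrate the proportional harvest rate
#'
#' Finds the constant yearly offtake h such that replicate projections
#' (catastrophes on, component feedback on) decline at the target rate.
#' A proportional harvest below the population's compensation capacity
#' merely shifts the equilibrium downward — the feedback re-stabilises the
#' population and the long-term trend returns to zero — so a persistently
#' declining population requires an offtake just beyond what compensation
#' can absorb.  The objective therefore measures the sustained decline:
#' the mean per-year r over the second half of the post-burn-in window
#' (`window = "late"`, default), after the initial adjustment away from
#' carrying capacity has played out.  `window = "full"` targets the mean
#' over the whole window instead (which a sub-capacity offtake can also
#' satisfy transiently, leaving the feedback active).  The objective uses
#' common random numbers across evaluations and is monotone decreasing in
#' h, so bisection converges cleanly.
#'
#' @param lh,L,fp,cp As in [project_series()].
#' @param target_mean_r Target sustained decline rate (e.g. -0.001 or
#'   -0.01).
#' @param tol Tolerance on the achieved mean r.
#' @param n_reps Replicates per evaluation.
#' @param rng_seed Root seed.
#' @param control A [project_control()].
#' @param window `"late"` (sustained rate, second half) or `"full"`.
#' @return The harvest proportion h.
#' @export
calibrate_harvest <- function(lh, L, fp, cp = catastrophe_params(),
                              target_mean_r, tol = 1e-3, n_reps = 100,
                              rng_seed = 1, control = project_control(),
                              window = c("late", "full")) {
  window <- match.arg(window)
  scen <- scenario_preset("ii")
  mean_r <- function(h) {
    scen$harvest_rate <- h
    rs <- unlist(lapply(seq_len(n_reps), function(i) {
      r <- project_series(lh, L, fp, scen, cp,
                         rng_seed = derive_seed(rng_seed, 0L, 4L, i),
                         control = control)$r
      if (window == "late" && length(r) > 3) {
        r <- r[seq.int(floor(length(r) / 2) + 1L, length(r))]
      }
      r
    }))
    m <- mean(rs, na.rm = TRUE)
    if (!is.finite(m)) m <- -1   # collapsed before burn-in ended
    m - target_mean_r
  }
  lo <- 0; hi <- 0.75
  f_lo <- mean_r(lo)
  # no offtake needed: already declining at the target (or, for a
  # stability target, within tolerance of it)
  if (f_lo <= if (target_mean_r == 0) tol else 0) return(0)
  f_hi <- mean_r(hi)
  if (f_hi > 0) stop("harvest calibration failed for ", lh$species$abbr,
                     ": target decline unreachable at h = 0.75")
  for (k in seq_len(30)) {
    mid <- (lo + hi) / 2
    f_mid <- mean_r(mid)
    if (abs(f_mid) < tol / 2 || (hi - lo) < 1e-4) break
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the catastrophe-hazard ramp for the null-feedback control
#'
#' With the component feedback switched off (S_red = 1) the population
#' grows at its intrinsic rate; in the null control the catastrophe hazard
#' rises linearly through the projection from its baseline,
#' C_t = (p_C / G) * (1 + s * (t - 1)), and this routine finds the ramp
#' rate s that brings the mean per-year growth rate over the horizon back
#' to ~0.  Populations then grow while the hazard is low and decline once
#' it exceeds the intrinsic growth rate, stable on average over 40
#' generations through purely density-independent mortality.  The
#' objective uses common random numbers and is monotone decreasing in s.
#'
#' @param lh,L As in [project_series()].
#' @param cp Baseline [catastrophe_params()].
#' @param tol Tolerance on the achieved mean r.
#' @param n_reps Replicates per evaluation.
#' @param rng_seed Root seed.
#' @param control A [project_control()].
#' @return The ramp rate s (per year, >= 0).
#' @export
calibrate_null_catastrophes <- function(lh, L, cp = catastrophe_params(),
                                        tol = 5e-4, n_reps = 12,
                                        rng_seed = 1,
                                        control = project_control()) {
  scen <- scenario_preset("ix")
  fp_null <- feedback_params(b = lh$K, applies_to = "none")
  mean_r <- function(slope) {
    cpx <- cp
    cpx$ramp_slope <- slope
    rs <- unlist(lapply(seq_len(n_reps), function(i) {
      project_series(lh, L, fp_null, scen, cpx,
                     rng_seed = derive_seed(rng_seed, 0L, 9L, i),
                     control = control)$r
    }))
    m <- mean(rs, na.rm = TRUE)
    if (!is.finite(m)) m <- -1   # collapsed before burn-in ended
    m
  }
  f0 <- mean_r(0)
  if (f0 <= 0) return(0)
  hi <- 0.05
  f_hi <- mean_r(hi)
  tries <- 0L
  while (f_hi > 0 && tries < 12) {
    hi <- hi * 4
    f_hi <- mean_r(hi)
    tries <- tries + 1L
  }
  if (f_hi > tol) {
    stop("null-feedback calibration failed for ", lh$species$abbr,
         ": growth cannot be offset even at a saturated hazard")
  }
  lo <- 0
  for (k in seq_len(45)) {
    mid <- (lo + hi) / 2
    f_mid <- mean_r(mid)
    if (abs(f_mid) < tol / 4 || (hi - lo) < 1e-8) break
    if (f_mid > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
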