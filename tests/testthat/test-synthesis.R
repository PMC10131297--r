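# Minimal per-series results table for aggregation tests.
fake_results <- function(strength, abbr = "AA", scenario = "ii",
                         comp = NULL) {
  n <- length(strength)
  data.frame(abbr = abbr, scenario = scenario, replicate = seq_len(n),
             extinct = FALSE, fittable = TRUE, n_transitions = 50,
             pr_density_feedback = 0.9, strength = strength,
             ricker_beta = -strength / 100,
             component_strength = if (is.null(comp)) strength / 2 else comp,
             mean_r = 0, mean_TR = 1, var_TR = 0.1, crossings = 10L,
             stationarity = 10, stringsAsFactors = FALSE)
}

test_that("species summaries use linear-interpolation percentiles", {
  res <- fake_results(1:100)
  s <- summarize_species(res, metrics = "strength")
  expect_equal(s$strength_median, 50.5)
  expect_equal(s$strength_lo, 3.475)
  expect_equal(s$strength_hi, 97.525)
  expect_true(s$reliable)
  # identical replicates give a zero-width interval
  s0 <- summarize_species(fake_results(rep(2, 10)), metrics = "strength")
  expect_equal(s0$strength_lo, s0$strength_hi)
  # too few usable series are flagged
  s2 <- summarize_species(fake_results(c(1, 2)), metrics = "strength")
  expect_false(s2$reliable)
})

test_that("interval ordering lower <= median <= upper holds", {
  set.seed(20)
  res <- do.call(rbind, lapply(letters[1:6], function(ab) {
    fake_results(rnorm(50, 1), abbr = ab)
  }))
  s <- summarize_species(res)
  for (mt in c("strength", "component_strength")) {
    expect_true(all(s[[paste0(mt, "_lo")]] <= s[[paste0(mt, "_median")]]))
    expect_true(all(s[[paste0(mt, "_median")]] <= s[[paste0(mt, "_hi")]]))
  }
})

# Summary table for n species with chosen interval half-widths.
fake_summary <- function(x, y, wx = 0, wy = 0) {
  data.frame(abbr = sprintf("s%02d", seq_along(x)), scenario = "ii",
             n_usable = 100, reliable = TRUE,
             component_strength_median = x,
             component_strength_lo = x - wx, component_strength_hi = x + wx,
             strength_median = y, strength_lo = y - wy,
             strength_hi = y + wy, stringsAsFactors = FALSE)
}

test_that("the Spearman bootstrap collapses correctly in degenerate cases", {
  x <- seq(0.1, 1, length.out = 10)
  y <- x^2
  # zero-width intervals + strict monotonicity: every draw gives rho = 1
  b <- bootstrap_spearman(fake_summary(x, y), "component_strength",
                          "strength", n_boot = 200, rng_seed = 1)
  expect_equal(b$rho_median, 1)
  expect_equal(b$rho_lower, 1)
  # zero-width intervals equal the plain Spearman of the point estimates
  y2 <- c(3, 1, 4, 1.5, 5, 9, 2.6, 5.3, 5.8, 9.7)
  b2 <- bootstrap_spearman(fake_summary(x, y2), "component_strength",
                           "strength", n_boot = 100, rng_seed = 1)
  expect_equal(b2$rho_median, cor(x, y2, method = "spearman"))
  expect_error(bootstrap_spearman(fake_summary(x[1:4], y[1:4]),
                                  "component_strength", "strength"),
               "at least 5")
})

test_that("huge interval noise drives the bootstrap correlation to zero", {
  x <- seq(0.1, 1, length.out = 21)
  b <- bootstrap_spearman(fake_summary(x, x, wx = 100, wy = 100),
                          "component_strength", "strength",
                          n_boot = 2000, rng_seed = 2)
  expect_lt(abs(b$rho_median), 0.25)
  expect_lt(b$rho_lower, 0)
  expect_gt(b$rho_upper, 0)
})

test_that("the bootstrap is seed-reproducible and stable in n_boot", {
  set.seed(21)
  x <- runif(21)
  y <- x + rnorm(21, 0, 0.2)
  s <- fake_summary(x, y, wx = 0.1, wy = 0.1)
  b1 <- bootstrap_spearman(s, "component_strength", "strength",
                           n_boot = 2000, rng_seed = 5)
  b2 <- bootstrap_spearman(s, "component_strength", "strength",
                           n_boot = 2000, rng_seed = 5)
  expect_identical(b1$rho_median, b2$rho_median)
  b4 <- bootstrap_spearman(s, "component_strength", "strength",
                           n_boot = 4000, rng_seed = 5)
  expect_lt(abs(b4$rho_median - b1$rho_median), 0.01)
})

test_that("plateau fits recover known parameters", {
  x <- seq(0, 3, length.out = 50)
  y <- 2 - (2 - 0) * exp(-1 * x)
  pf <- fit_plateau(x, y)
  expect_true(pf$converged)
  expect_equal(pf$y0, 0, tolerance = 1e-6)
  expect_equal(pf$ymax, 2, tolerance = 1e-6)
  expect_equal(pf$k_rate, 1, tolerance = 1e-6)
  # noisy recovery within 15%
  set.seed(22)
  yn <- y + rnorm(50, 0, 0.05)
  pfn <- fit_plateau(x, yn)
  expect_true(pfn$converged)
  expect_lt(abs(pfn$k_rate - 1) / 1, 0.15)
  # flat data: rate unidentifiable, flagged instead of invented
  pf0 <- fit_plateau(x, rep(1.3, 50))
  expect_false(pf0$converged)
  expect_error(fit_plateau(1:3, 1:3), "at least 4")
})

test_that("the scenario report is a pure function of the results table", {
  set.seed(23)
  res <- do.call(rbind, lapply(sprintf("s%02d", 1:8), function(ab) {
    st <- rnorm(30, runif(1, 0.05, 0.3), 0.05)
    out <- fake_results(st, abbr = ab, comp = st / 2 + rnorm(30, 0, 0.02))
    out
  }))
  r1 <- scenario_report(res, n_boot = 500, rng_seed = 3)
  r2 <- scenario_report(res, n_boot = 500, rng_seed = 3)
  expect_identical(r1$scenario_table, r2$scenario_table)
  expect_identical(r1$species_summary, r2$species_summary)
  expect_true(all(c("median_pr_feedback", "detection_rate",
                    "rho_component_ensemble") %in%
                    names(r1$scenario_table)))
})
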