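test_that("the survival modifier matches its closed form", {
  p <- feedback_params(a = 1, b = 1000, c = 2)
  expect_equal(s_red(0, p), 1.0)
  expect_equal(s_red(1000, p), 0.5)
  expect_equal(s_red(2000, p), 0.2)
  expect_error(s_red(-1, p), "non-negative")
})

test_that("s_red is non-increasing in abundance for any positive a, b, c", {
  set.seed(42)
  for (k in 1:25) {
    p <- feedback_params(a = runif(1, 0.2, 1), b = 10^runif(1, 1, 6),
                         c = runif(1, 0.2, 5))
    n <- sort(10^runif(40, 0, 7))
    v <- s_red(n, p)
    expect_true(all(diff(v) <= 1e-15))
    expect_true(all(v > 0 & v <= p$a))
  }
})

test_that("apply_feedback multiplies and clips; null feedback is identity", {
  p <- feedback_params(a = 1, b = 1000, c = 2)
  expect_equal(apply_feedback(c(0.8, 0.9), 1000, p), c(0.40, 0.45))
  expect_equal(apply_feedback(c(0.8, 0.9), 0, p), c(0.8, 0.9))
  pn <- feedback_params(a = 1, b = 1000, c = 2, applies_to = "none")
  expect_equal(apply_feedback(c(0.8, 0.9), 1e9, pn), c(0.8, 0.9))
})

test_that("component strength summarises the modifier trace", {
  expect_equal(component_strength(rep(1, 10)), 0)
  expect_equal(component_strength(rep(0.8, 10)), 0.2)
  expect_equal(component_strength(c(1.0, 0.6)), 0.2)
  expect_error(component_strength(numeric(0)), "empty")
})

test_that("calibrated feedback stabilises populations at carrying capacity", {
  f <- fx_lh("SH")
  cal <- fx_cal("SH")
  expect_true(cal$record$converged)
  expect_lte(abs(cal$record$achieved_mean_r), 0.002)
  stats <- vapply(1:100, function(i) {
    s <- project_series(f$lh, f$L, cal$params, scenario_preset("i"),
                        rng_seed = derive_seed(5, 1, 1, i))
    c(mean(s$r, na.rm = TRUE), mean(s$N, na.rm = TRUE))
  }, numeric(2))
  # grand mean yearly growth rate over 100 replicate series
  expect_lte(abs(mean(stats[1, ])), 0.005)
  # long-run abundance within 15% of K
  expect_lt(abs(mean(stats[2, ]) / f$lh$K - 1), 0.15)
})

test_that("calibration reports infeasibility when lambda < 1 at S_red = a", {
  lh <- structure(list(species = list(abbr = "sink", q_yr = 40),
                       omega = 1L, maturity = 1L,
                       S = c(0.3, 0), m = c(0, 1),  # lambda ~ 0.55
                       terminal_survival_zeroed = TRUE,
                       D = 0.004, A = 250000, K = 1000),
                  class = "life_history")
  expect_warning(out <- calibrate_feedback(lh, build_leslie(lh)),
                 "infeasible")
  expect_false(out$record$converged)
})

test_that("mean component strength is set by the life history, not by c", {
  # the equilibrium modifier is pinned by the growth-rate balance, so the
  # per-series mean of 1 - S_red barely moves across steepness values ...
  f <- fx_lh("VU")
  strengths <- vapply(c(1, 2, 3), function(cc) {
    cal <- calibrate_feedback(f$lh, f$L, c_exponent = cc, rng_seed = 7)
    mean(vapply(1:20, function(i) {
      component_strength(project_series(f$lh, f$L, cal$params,
                                        scenario_preset("i"),
                                        rng_seed = derive_seed(3, 1, 1, i)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(diff(range(strengths)), 0.01)
  # ... while the local response of the modifier steepens with c: at a
  # matched equilibrium value, a 5% abundance rise suppresses survival more
  # for larger c
  f_star <- 0.9
  drop <- vapply(c(1, 2, 3), function(cc) {
    b <- 1e5 / (1 / f_star - 1)^(1 / cc)
    p <- feedback_params(a = 1, b = b, c = cc)
    s_red(1e5, p) - s_red(1.05e5, p)
  }, numeric(1))
  expect_true(all(diff(drop) > 0))
})

test_that("splitting the feedback onto fertility preserves the lambda effect", {
  f <- fx_lh("VU")
  cal <- fx_cal("VU")
  p <- cal$params
  expect_identical(split_feedback_with_fertility(p, 0, f$L), p)
  p1 <- split_feedback_with_fertility(p, 1, f$L)
  expect_equal(p1$surv_exponent, 0)
  expect_gt(p1$fert_exponent, 0)
  expect_error(split_feedback_with_fertility(p, 1.2, f$L), "0, 1")

  v <- s_red(f$lh$K, p)  # equilibrium modifier
  lam_surv <- build_leslie(list(S = pmin(f$lh$S * v, 1),
                                m = f$lh$m))$lambda1
  p5 <- split_feedback_with_fertility(p, 0.5, f$L)
  lam_split <- build_leslie(list(
    S = pmin(f$lh$S * v^p5$surv_exponent, 1),
    m = f$lh$m * v^p5$fert_exponent))$lambda1
  expect_lt(abs(lam_split - lam_surv) / lam_surv, 0.05)
})

test_that("calibrated parameters persist as structured text", {
  cal <- fx_cal("SH")
  tmp <- tempfile(fileext = ".csv")
  write_feedback_params(list(SH = list(params = cal$params,
                                       record = cal$record)), tmp)
  back <- read_feedback_params(tmp)[["SH"]]
  expect_equal(back$b, cal$params$b)
  expect_equal(back$c, cal$params$c)
})
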