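test_that("growth rates are log-ratios over positive transitions", {
  gr <- growth_rates(c(100, 110), min_transitions = 1)
  expect_equal(gr$r, log(1.1))
  expect_equal(growth_rates(rep(50, 10), min_transitions = 1)$r, rep(0, 9))
  gr0 <- growth_rates(c(100, 0, 50, 60), min_transitions = 1)
  expect_equal(gr0$n_dropped, 2)
  expect_equal(gr0$r, log(60 / 50))
  expect_false(growth_rates(c(100, 110), min_transitions = 30)$fittable)
})

test_that("least squares recovers exact linear structure to machine precision", {
  set.seed(10)
  N <- runif(10, 50, 500)
  r <- 0.4 - 0.002 * N
  f <- fit_model(r, N, "ricker")
  expect_equal(f$alpha_hat, 0.4, tolerance = 1e-12)
  expect_equal(f$beta_hat, -0.002, tolerance = 1e-12)
  rg <- 0.9 - 0.15 * log(N)
  g <- fit_model(rg, N, "gompertz")
  expect_equal(g$beta_hat, -0.15, tolerance = 1e-12)
  expect_error(fit_model(rnorm(4), runif(4), "ricker"), "too few")
})

test_that("least squares agrees with a normal-equations oracle", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(20:60, 1)
    N <- exp(rnorm(n, 6, 0.5))
    r <- rnorm(n, 0, 0.2)
    for (mod in c("ricker", "gompertz")) {
      x <- if (mod == "ricker") N else log(N)
      X <- cbind(1, x)
      ab <- solve(crossprod(X), crossprod(X, r))
      f <- fit_model(r, N, mod)
      expect_equal(f$alpha_hat, ab[1], tolerance = 1e-10)
      expect_equal(f$beta_hat, ab[2], tolerance = 1e-10)
    }
  }
})

test_that("the random walk wins on density-independent noise", {
  set.seed(12)
  wins <- vapply(1:400, function(k) {
    n <- 50
    N <- exp(rnorm(n, 7, 0.4))
    r <- rnorm(n, 0, 0.15)
    fits <- lapply(c("random_walk", "exponential", "ricker", "gompertz"),
                   function(m) fit_model(r, N, m))
    aiccs <- vapply(fits, `[[`, numeric(1), "AICc")
    which.min(aiccs) == 1
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("AICc arithmetic matches the closed form", {
  expect_equal(aicc(-50, 3, 40), 106 + 2 / 3, tolerance = 1e-12)
  expect_equal(aicc(-50, 0, 40), 100)
  expect_error(aicc(-50, 3, 4), "n must exceed")
  # the small-sample correction vanishes as n grows
  expect_equal(aicc(-50, 3, 1e8), -2 * -50 + 6, tolerance = 1e-4)
})

test_that("Akaike weights normalise, rank and shift-invariantly weigh", {
  expect_equal(akaike_weights(rep(100, 4)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-6)
  expect_equal(round(w, 3), c(0.731, 0.269))
  wd <- akaike_weights(c(10, 30, 31, 35))
  expect_gt(wd[1], 0.9999)
  set.seed(13)
  a <- runif(4, 90, 110)
  expect_lt(abs(sum(akaike_weights(a)) - 1), 1e-12)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3),
               tolerance = 1e-12)
})

test_that("ensemble result combines weights and negates the Gompertz slope", {
  fits <- list(
    random_walk = fit_model(rnorm(40, 0, 0.1), exp(rnorm(40, 5, 0.3)),
                            "random_walk"))
  N <- exp(rnorm(40, 5, 0.3))
  r <- 0.5 - 0.2 * log(N) + rnorm(40, 0, 1e-8)
  fits <- lapply(setNames(PHENO_MODELS, PHENO_MODELS),
                 function(m) fit_model(r, N, m))
  er <- ensemble_result(fits, weights = setNames(rep(0.25, 4), PHENO_MODELS))
  expect_equal(er$pr_density_feedback, 0.5)
  expect_equal(er$strength, 0.2, tolerance = 1e-6)
})

test_that("strength is scale-invariant; the Ricker slope scales inversely", {
  set.seed(14)
  N <- exp(rnorm(50, 6, 0.4))
  r <- 0.3 - 0.05 * log(N) + rnorm(50, 0, 0.05)
  g1 <- fit_model(r, N, "gompertz")
  g2 <- fit_model(r, 10 * N, "gompertz")
  expect_equal(g1$beta_hat, g2$beta_hat, tolerance = 1e-10)
  r1 <- fit_model(r, N, "ricker")
  r2 <- fit_model(r, 10 * N, "ricker")
  expect_equal(r1$beta_hat, 10 * r2$beta_hat, tolerance = 1e-10)
})

test_that("full model comparison flags unfittable and degenerate input", {
  expect_error(fit_phenomenological(c(100, 110, 120)), "not fittable")
  # constant abundance: feedback predictors are degenerate
  expect_warning(out <- fit_phenomenological(rep(100, 40)), "degenerate")
  expect_false(out$fits$ricker$ok)
  expect_equal(sum(out$weights), 1, tolerance = 1e-12)
  expect_equal(unname(out$weights[c("ricker", "gompertz")]), c(0, 0))
})

test_that("a compensatory simulated series is detected with high probability", {
  f <- fx_lh("SH")
  cal <- fx_cal("SH")
  prs <- vapply(1:10, function(i) {
    s <- project_series(f$lh, f$L, cal$params, scenario_preset("i"),
                        rng_seed = derive_seed(17, 1, 1, i))
    fit_phenomenological(s)$ensemble$pr_density_feedback
  }, numeric(1))
  expect_gte(sum(prs > 0.5), 9)   # true positive in >= 9 of 10 series
})
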