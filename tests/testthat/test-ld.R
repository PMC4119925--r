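test_that("survival curve is 1 at dose zero and matches the coefficient form", {
  fit <- nb_pspline(make_counts())
  expect_equal(survival_curve(fit, "A", 0)$fraction, 1)

  doses <- c(0, 1, 3, 7, 12, 20)
  got <- survival_curve(fit, "A", doses)
  sm <- fit$design$smooths[["A"]]
  B <- splines::splineDesign(sm$basis$knots, sqrt(doses),
                             ord = sm$basis$degree + 1, outer.ok = TRUE)
  f <- drop(B %*% sm$Z %*% fit$coefficients[sm$cols])
  expect_equal(got$fraction, exp(f - f[1]), tolerance = 1e-12)

  expect_error(survival_curve(fit, "nope", 0:3), "unknown strain")
})

test_that("inversion recovers closed-form lethal doses of an exponential", {
  # fraction(d) = exp(-d log 2): LD50 = 1, LD10 = log(10)/log(2)
  frac <- function(d) exp(-d * log(2))
  r50 <- lethaldose:::invert_survival(frac, 0.5, d_max = 10)
  expect_false(r50$censored)
  expect_equal(r50$ld, 1, tolerance = 1e-5)
  r10 <- lethaldose:::invert_survival(frac, 0.1, d_max = 10)
  expect_equal(r10$ld, log(10) / log(2), tolerance = 1e-5)

  flat <- lethaldose:::invert_survival(function(d) rep(1, length(d)), 0.5,
                                       d_max = 10)
  expect_true(flat$censored)
  expect_equal(flat$ld, 10)
})

test_that("estimate_ld validates levels and respects censoring", {
  fit <- nb_pspline(make_flat_counts())
  expect_error(estimate_ld(fit, levels = 1.2), "between 0 and 1")
  est <- estimate_ld(fit)
  expect_true(all(est$censored))
  expect_equal(est$ld, est$d_max)
})

test_that("grid-plus-bisection inversion agrees with a brute-force scan", {
  for (s in c(2, 13)) {
    sim <- simulate_tolerance(seed = s)
    fit <- suppressWarnings(nb_pspline(sim))
    est <- estimate_ld(fit)
    for (i in seq_len(nrow(est))) {
      if (est$censored[i]) next
      d_max <- est$d_max[i]
      grid <- seq(0, d_max, length.out = 1e6)
      fr <- survival_curve(fit, est$strain[i], grid)$fraction
      brute <- grid[which(fr <= est$level[i])[1]]
      expect_lt(abs(est$ld[i] - brute), 1e-4 * d_max)
    }
  }
})

test_that("LD10 is at least LD50 on monotone fitted curves", {
  for (s in 1:8) {
    sim <- simulate_tolerance(seed = 100 + s)
    fit <- suppressWarnings(nb_pspline(sim))
    est <- estimate_ld(fit)
    wide <- tidyr::pivot_wider(est[, c("strain", "level", "ld")],
                               names_from = "level", values_from = "ld")
    expect_true(all(wide$`0.1` >= wide$`0.5` - 1e-8))
  }
})

test_that("bootstrap is reproducible bitwise from its seed", {
  sim <- simulate_tolerance(seed = 4)
  fit <- nb_pspline(sim)
  b1 <- ld_bootstrap(fit, n_boot = 2, seed = 99)
  b2 <- ld_bootstrap(fit, n_boot = 2, seed = 99)
  expect_identical(b1$draws, b2$draws)

  b3 <- ld_bootstrap(fit, n_boot = 25, seed = 99)
  b4 <- ld_bootstrap(fit, n_boot = 25, seed = 99)
  expect_identical(ld_confint(b3), ld_confint(b4))
})

test_that("bootstrap LD spread shrinks as counts grow in the Poisson limit", {
  pars <- tibble::tibble(strain = "A", shoulder = 0, decay_rate = 0.2,
                         smoothness = 0.01)
  width <- function(baseline, seed) {
    sim <- simulate_tolerance(strains = pars,
                              dose_grid = c(0, 1, 2, 4, 6, 9, 12, 16),
                              baseline_count = baseline,
                              experiment_effect_sd = 0, theta = 1e8,
                              seed = seed)
    fit <- nb_pspline(sim, theta = 1e8)
    boot <- ld_bootstrap(fit, levels = 0.5, n_boot = 99, seed = seed + 1)
    ci <- ld_confint(boot)
    ci$ci_high - ci$ci_low
  }
  expect_lt(width(1e6, 31), width(1e4, 31))
})

test_that("confidence intervals follow the draw distribution", {
  est <- tibble::tibble(strain = "A", level = 0.5, ld = 5, censored = FALSE,
                        d_max = 100)
  # degenerate draws collapse the interval
  drw <- tibble::tibble(replicate = 1:50, strain = "A", level = 0.5,
                        ld = 7, censored = FALSE)
  boot <- lethaldose:::new_ld_boot(drw, est, 50, 0L, 1, c(A = 100), 0.5)
  ci <- ld_confint(boot)
  expect_equal(ci$ci_low, 7)
  expect_equal(ci$ci_high, 7)

  # uniform draws reproduce the percentile oracle
  set.seed(8)
  u <- runif(1000)
  drw2 <- tibble::tibble(replicate = 1:1000, strain = "A", level = 0.5,
                         ld = u, censored = FALSE)
  boot2 <- lethaldose:::new_ld_boot(drw2, est, 1000, 0L, 1, c(A = 100), 0.5)
  ci2 <- ld_confint(boot2)
  # order-statistic tolerance: ~3 SE of the 2.5th percentile of 1000 draws
  expect_lt(abs(ci2$ci_low - 0.025), 0.015)
  expect_lt(abs(ci2$ci_high - 0.975), 0.015)
  expect_equal(ci2$ci_low, unname(quantile(u, 0.025)), tolerance = 1e-12)

  # point estimate lies inside the interval on simulation fixtures
  sim <- simulate_tolerance(seed = 6)
  fit <- nb_pspline(sim)
  bt <- ld_bootstrap(fit, n_boot = 49, seed = 7)
  cif <- ld_confint(bt)
  expect_true(all(cif$ci_low <= cif$ld + 1e-8 &
                    cif$ld <= cif$ci_high + 1e-8))
})

test_that("censored draws enter order statistics at d_max and flag bounds", {
  est <- tibble::tibble(strain = "A", level = 0.5, ld = 80, censored = FALSE,
                        d_max = 100)
  drw <- tibble::tibble(replicate = 1:20, strain = "A", level = 0.5,
                        ld = c(seq(50, 95, length.out = 10), rep(100, 10)),
                        censored = rep(c(FALSE, TRUE), each = 10))
  boot <- lethaldose:::new_ld_boot(drw, est, 20, 0L, 1, c(A = 100), 0.5)
  ci <- ld_confint(boot)
  expect_true(ci$ci_high_censored)
  expect_false(ci$ci_low_censored)
  expect_equal(ci$ci_high, 100)
})

test_that("strain contrasts are antisymmetric and flag constant shifts", {
  make_draws <- function(ld_a, ld_b, cens_a = FALSE, cens_b = FALSE) {
    n <- length(ld_a)
    dplyr::bind_rows(
      tibble::tibble(replicate = 1:n, strain = "A", level = 0.5, ld = ld_a,
                     censored = rep_len(cens_a, n)),
      tibble::tibble(replicate = 1:n, strain = "B", level = 0.5, ld = ld_b,
                     censored = rep_len(cens_b, n))
    )
  }
  est <- tibble::tibble(strain = c("A", "B"), level = 0.5, ld = c(7, 5),
                        censored = FALSE, d_max = 100)
  # constant shift of 2
  boot <- lethaldose:::new_ld_boot(make_draws(rep(7, 30), rep(5, 30)), est,
                                   30, 0L, 1, c(A = 100, B = 100), 0.5)
  ctr <- ld_contrast(boot, "A", "B")
  expect_equal(ctr$ci_low, 2)
  expect_equal(ctr$ci_high, 2)
  expect_true(ctr$significant)

  # antisymmetry, replicate-wise
  set.seed(12)
  boot2 <- lethaldose:::new_ld_boot(make_draws(runif(40, 4, 9),
                                               runif(40, 3, 8)),
                                    est, 40, 0L, 1,
                                    c(A = 100, B = 100), 0.5)
  ab <- ld_contrast(boot2, "A", "B")
  ba <- ld_contrast(boot2, "B", "A")
  expect_equal(ab$deltas[[1]], -ba$deltas[[1]])
  expect_equal(ab$delta, -ba$delta)

  # replicates censored for one strain are excluded and counted
  ld_a <- c(rep(7, 25), rep(100, 5))
  cens <- c(rep(FALSE, 25), rep(TRUE, 5))
  drw <- dplyr::bind_rows(
    tibble::tibble(replicate = 1:30, strain = "A", level = 0.5, ld = ld_a,
                   censored = cens),
    tibble::tibble(replicate = 1:30, strain = "B", level = 0.5,
                   ld = rep(5, 30), censored = FALSE)
  )
  boot3 <- lethaldose:::new_ld_boot(drw, est, 30, 0L, 1,
                                    c(A = 100, B = 100), 0.5)
  ctr3 <- ld_contrast(boot3, "A", "B")
  expect_equal(ctr3$n_excluded, 5)
  expect_equal(length(ctr3$deltas[[1]]), 25)
})

test_that("bootstrap input contracts are enforced", {
  sim <- simulate_tolerance(seed = 5)
  fit <- nb_pspline(sim)
  expect_error(ld_bootstrap(fit, n_boot = 1, seed = 1), "n_boot")
  expect_error(ld_bootstrap(fit, n_boot = 10), "seed")
  bad <- fit
  bad$converged <- FALSE
  expect_error(ld_bootstrap(bad, n_boot = 10, seed = 1), "converged")
})
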