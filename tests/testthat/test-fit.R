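test_that("no dose effect yields flat fitted survival and small smooth edf", {
  df <- make_flat_counts(100)
  fit <- nb_pspline(df)
  expect_true(fit$converged)
  curve <- survival_curve(fit, doses = c(0, 2, 5, 10, 20, 40))
  expect_equal(curve$fraction, rep(1, nrow(curve)), tolerance = 1e-8)
  # smooth effectively collapses to its penalty null space
  expect_true(all(fit$edf_by_strain < 1.5))
})

test_that("fit recovers a known log-linear truth in sqrt dose", {
  # log mu = 5 - 0.8 * sqrt(d), Poisson noise, n = 400, lambda near zero.
  # The unpenalized spline interpolates noise (pointwise log-scale SE up to
  # ~0.1 at the sparse high-dose end), so truth recovery is asserted at a
  # Monte-Carlo-consistent bound and the exact check is equivalence with an
  # independent penalized-Poisson IRLS oracle on the same design.
  set.seed(11)
  doses <- rep(seq(0, 25, length.out = 50), each = 8)
  mu <- exp(5 - 0.8 * sqrt(doses))
  df <- tibble::tibble(strain = "A", experiment = "e1", dose = doses,
                       count = rpois(length(doses), mu))
  fit <- nb_pspline(df, lambda = 1e-8)
  grid <- seq(0, 25, length.out = 101)
  pred <- predict_mean(fit, "A", "e1", grid)
  err <- abs(log(pred$mean) - (5 - 0.8 * sqrt(grid)))
  expect_lt(max(err), 0.25)
  expect_lt(mean(err), 0.08)
  expect_gt(fit$theta, 1e4)  # Poisson data: little overdispersion

  oracle <- poisson_penalized_fit(fit$design$X, fit$y, fit$design$Slist,
                                  1e-8)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-5)
})

test_that("lambda -> 0 with saturated basis matches an unpenalized NB GLM", {
  skip_if_not_installed("MASS")
  set.seed(5)
  doses <- c(0, 1, 4, 9, 16, 25)
  df <- tidyr::expand_grid(strain = c("A", "B"), experiment = c("e1", "e2"),
                           dose = doses, rep = 1:2)
  truth <- exp(6 - 0.5 * sqrt(df$dose) + 0.3 * (df$strain == "B"))
  df$count <- rnbinom(nrow(df), size = 8, mu = truth)
  df <- df[, c("strain", "experiment", "dose", "count")]

  fit <- nb_pspline(df, num_basis = 6, lambda = 0)
  glmdf <- data.frame(y = round(df$count),
                      grp = interaction(df$strain, df$experiment),
                      strain = factor(df$strain),
                      dosef = factor(df$dose))
  ref <- MASS::glm.nb(y ~ grp + strain:dosef, data = glmdf)
  expect_equal(unname(fit$fitted), unname(fitted(ref)), tolerance = 1e-6)
})

test_that("theta = 1e8 fit matches a penalized Poisson fit", {
  df <- make_counts()
  fit <- nb_pspline(df, lambda = c(1, 1), theta = 1e8)
  oracle <- poisson_penalized_fit(fit$design$X, fit$y, fit$design$Slist,
                                  c(1, 1))
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)
})

test_that("penalized deviance is non-increasing across IRLS iterations", {
  df <- make_counts()
  fit <- nb_pspline(df, lambda = c(0.5, 2), theta = 10)
  tr <- fit$dev_trace
  expect_true(all(diff(tr) <= 1e-8 * (abs(tr[-length(tr)]) + 0.1)))
})

test_that("smoothing selection is deterministic and tracks curvature", {
  sim <- simulate_tolerance(seed = 3)
  l1 <- select_smoothing(sim)
  l2 <- select_smoothing(sim)
  expect_identical(l1, l2)

  # pure-noise dose effect: heaviest smoothing, edf near null-space dim
  set.seed(21)
  flat <- tibble::tibble(
    strain = rep("A", 48), experiment = rep(c("e1", "e2"), each = 24),
    dose = rep(c(0, 2, 5, 10, 20, 40), 8),
    count = rnbinom(48, size = 10, mu = 500)
  )
  fitf <- nb_pspline(flat)
  expect_gte(unname(fitf$lambda["A"]), 1e4)
  expect_lt(unname(fitf$edf_by_strain["A"]), 1.5)

  # strongly curved truth at large n: selected lambda interior to the grid
  set.seed(22)
  doses <- rep(seq(0, 36, length.out = 25), each = 16)
  mu <- 5e4 * exp(-((sqrt(doses) - 3)^2))
  curved <- tibble::tibble(strain = "A", experiment = "e1", dose = doses,
                           count = rnbinom(length(doses), size = 20, mu = mu))
  fitc <- nb_pspline(curved)
  expect_gt(unname(fitc$lambda["A"]), 1e-4)
  expect_lt(unname(fitc$lambda["A"]), 1e6)
})

test_that("predictions are consistent with stored fitted values and bases", {
  df <- make_counts()
  fit <- nb_pspline(df)

  empty <- predict_mean(fit, "A", "e1", numeric(0))
  expect_equal(nrow(empty), 0)

  pred_rows <- predict(fit)
  expect_equal(unname(pred_rows), unname(fit$fitted), tolerance = 1e-10)

  # explicit basis-times-coefficient oracle on a fine grid
  grid <- seq(0, 20, length.out = 41)
  sm <- fit$design$smooths[["A"]]
  B <- splines::splineDesign(sm$basis$knots, sqrt(grid),
                             ord = sm$basis$degree + 1, outer.ok = TRUE)
  f <- drop(B %*% sm$Z %*% fit$coefficients[sm$cols])
  eta0 <- fit$coefficients[["(Intercept)"]]
  expect_equal(predict_mean(fit, "A", "e1", grid)$mean,
               exp(eta0 + f), tolerance = 1e-10)

  expect_error(predict_mean(fit, "Z", "e1", 1), "unknown strain")
  expect_error(predict_mean(fit, "A", "e9", 1), "unknown experiment")
})

test_that("count rescaling shifts the intercept and leaves fractions unchanged", {
  # In the Poisson limit the rescaled objective is exactly proportional to
  # the original (penalty rescaled alike), so the fit shifts only in the
  # intercept, by exactly log k.
  sim <- simulate_tolerance(seed = 9, theta = 1e8, baseline_count = 1e5)
  scaled <- sim
  scaled$count <- scaled$count * 8
  fit1 <- nb_pspline(sim, lambda = c(1, 1), theta = 1e8)
  fit2 <- nb_pspline(scaled, lambda = c(8, 8), theta = 1e8)
  expect_equal(fit2$coefficients[["(Intercept)"]] -
                 fit1$coefficients[["(Intercept)"]],
               log(8), tolerance = 1e-4)
  expect_equal(fit2$coefficients[-1], fit1$coefficients[-1],
               tolerance = 1e-3)
  doses <- c(0, 2, 5, 10, 20, 40, 60)
  expect_equal(survival_curve(fit2, doses = doses)$fraction,
               survival_curve(fit1, doses = doses)$fraction,
               tolerance = 1e-3)

  # With estimated NB dispersion the property is approximate (scaled counts
  # are slightly more dispersed than any NB at the scaled mean), but the
  # fractions still track closely.
  nb1 <- nb_pspline(sim)
  nbs <- sim
  nbs$count <- nbs$count * 3
  nb2 <- nb_pspline(nbs)
  expect_equal(nb2$coefficients[["(Intercept)"]] -
                 nb1$coefficients[["(Intercept)"]],
               log(3), tolerance = 0.05)
  expect_equal(survival_curve(nb2, doses = doses)$fraction,
               survival_curve(nb1, doses = doses)$fraction,
               tolerance = 0.05)
})

test_that("degenerate all-zero strains are rejected", {
  df <- make_counts()
  df$count[df$strain == "B"] <- 0
  expect_error(nb_pspline(df), "all counts are zero.*B")
})

test_that("fitted log-survival error shrinks with sample size", {
  pars <- tibble::tibble(strain = "A", shoulder = 2, decay_rate = 0.15,
                         smoothness = 1)
  sup_err <- function(n_rep, seeds) {
    vapply(seeds, function(s) {
      sim <- simulate_tolerance(strains = pars,
                                dose_grid = c(0, 1, 5, 10, 20, 40, 60, 120),
                                experiments = 2, plate_replicates = n_rep,
                                baseline_count = 1e4, theta = 5, seed = s)
      fit <- nb_pspline(sim)
      doses <- c(0, 1, 5, 10, 20, 40, 60)
      est <- log(survival_curve(fit, doses = doses)$fraction)
      tru <- log(shoulder_survival(doses, 2, 0.15, 1))
      max(abs(est - tru))
    }, numeric(1))
  }
  seeds <- 1:40
  err_small <- sup_err(1, seeds)   # n = 16 rows
  err_large <- sup_err(10, seeds)  # n = 160 rows
  expect_lt(median(err_large), median(err_small))
})

test_that("tidy and glance summarise the fit", {
  fit <- nb_pspline(make_counts())
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "type", "strain") %in% names(td)))
  expect_equal(nrow(td), length(fit$coefficients))
  expect_setequal(unique(td$strain[td$type == "smooth"]), c("A", "B"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 32)
  expect_true(gl$converged)
})
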