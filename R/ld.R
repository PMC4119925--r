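#' Model-based survival curve
#'
#' The survival fraction at dose d is the ratio of the predicted mean count
#' at d to the predicted mean at dose 0, holding the experiment at its
#' reference level. Under the nested fixed-effect design all parametric
#' terms cancel in the ratio, so the fraction is
#' \eqn{\exp(f_s(\sqrt d) - f_s(0))} and equals 1 exactly at dose 0. The
#' model baseline (dose-0 prediction) is used rather than the observed
#' dose-0 mean because the model absorbs the unknown inoculum into the
#' intercept.
#'
#' @param fit A fitted `"nb_pspline"` model.
#' @param strain Strain identifier; default all fitted strains.
#' @param doses Non-negative, sorted dose vector.
#' @return Tibble with columns `strain`, `dose`, `fraction`.
#' @export
survival_curve <- function(fit, strain = NULL, doses) {
  stopifnot(inherits(fit, "nb_pspline"))
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  strains <- if (is.null(strain)) fit$design$strains else strain
  purrr::map_dfr(strains, function(s) {
    f <- smooth_value(fit$design, fit$coefficients, s, sqrt(doses))
    f0 <- smooth_value(fit$design, fit$coefficients, s, 0)
    tibble::tibble(strain = s, dose = doses, fraction = exp(f - f0))
  })
}

# Fraction as a function of dose for one strain, as a closure over the
# design; used by the inversion routines.
fraction_fun <- function(design, beta, strain) {
  sm <- design$smooths[[strain]]
  if (is.null(sm)) stop("unknown strain: ", strain, call. = FALSE)
  b <- beta[sm$cols]
  f0 <- drop(smooth_rows(design, strain, 0) %*% b)
  function(d) exp(drop(smooth_rows(design, strain, sqrt(d)) %*% b) - f0)
}

# Invert a survival-fraction function: smallest dose with fraction <= p,
# located by a scan on an `n_grid`-point uniform grid in sqrt-dose followed
# by interval bisection (64-ary, vectorised over the bracket) down to
# |interval| < d_max * 1e-6 in dose units.  `grid_frac` optionally supplies
# precomputed fractions on the standard grid (bootstrap hot path).
# Returns list(ld, censored).
invert_survival <- function(frac, p, d_max, n_grid = 512,
                            grid_frac = NULL) {
  u <- seq(0, sqrt(d_max), length.out = n_grid)
  fr <- if (is.null(grid_frac)) frac(u^2) else grid_frac
  idx <- which(fr <= p)
  if (length(idx) == 0) return(list(ld = d_max, censored = TRUE))
  i <- idx[1]
  if (i == 1) return(list(ld = 0, censored = FALSE))
  u_lo <- u[i - 1]
  u_hi <- u[i]
  tol <- d_max * 1e-6
  while (u_hi^2 - u_lo^2 > tol) {
    uu <- seq(u_lo, u_hi, length.out = 65)
    ff <- frac(uu^2)
    j <- which(ff <= p)[1]
    if (is.na(j) || j == 1) break  # numerical tie at the bracket edge
    u_lo <- uu[j - 1]
    u_hi <- uu[j]
  }
  list(ld = (u_lo^2 + u_hi^2) / 2, censored = FALSE)
}

# Precompute, per strain, the scan grid and the linear-form matrices that
# map spline coefficients to log survival on that grid (the design is fixed
# across bootstrap replicates, so this is done once).
ld_grid_cache <- function(design, d_max, n_grid = 512) {
  out <- list()
  for (s in design$strains) {
    u <- seq(0, sqrt(d_max[[s]]), length.out = n_grid)
    out[[s]] <- list(
      M = smooth_rows(design, s, u),
      m0 = drop(smooth_rows(design, s, 0))
    )
  }
  out
}

# LD values for all strains/levels from raw design + coefficients (used both
# for the original fit and for bootstrap refits; kept allocation-light as it
# runs once per bootstrap replicate).
ld_from_coefs <- function(design, beta, levels, d_max, cache = NULL) {
  if (is.null(cache)) cache <- ld_grid_cache(design, d_max)
  ns <- length(design$strains)
  nl <- length(levels)
  n <- ns * nl
  strain_out <- character(n)
  level_out <- numeric(n)
  ld_out <- numeric(n)
  cens_out <- logical(n)
  k <- 1
  for (s in design$strains) {
    sm <- design$smooths[[s]]
    b <- beta[sm$cols]
    frac <- fraction_fun(design, beta, s)
    grid_frac <- exp(drop(cache[[s]]$M %*% b) - sum(cache[[s]]$m0 * b))
    for (p in levels) {
      r <- invert_survival(frac, p, d_max[[s]], grid_frac = grid_frac)
      strain_out[k] <- s
      level_out[k] <- p
      ld_out[k] <- r$ld
      cens_out[k] <- r$censored
      k <- k + 1
    }
  }
  tibble::new_tibble(list(strain = strain_out, level = level_out,
                          ld = ld_out, censored = cens_out), nrow = n)
}

#' Lethal-dose point estimates
#'
#' For each strain and level p, finds the smallest dose at which the
#' model-based survival fraction drops to p (LD50 for p = 0.5, LD10 for
#' p = 0.1), by a 512-point grid scan in sqrt-dose followed by bisection to
#' a relative dose tolerance of 1e-6. When the fitted curve never reaches p
#' within the tested dose range the estimate is right-censored at `d_max`
#' (read as LDp > `d_max`); lethal doses are never extrapolated beyond the
#' design.
#'
#' @param fit A fitted `"nb_pspline"` model.
#' @param levels Survival levels p in (0, 1); default `c(0.5, 0.1)`.
#' @param d_max Optional named vector of maximum search doses per strain;
#'   default each strain's maximum observed dose.
#' @return Tibble with columns `strain`, `level`, `ld`, `censored`, `d_max`.
#' @export
estimate_ld <- function(fit, levels = c(0.5, 0.1), d_max = NULL) {
  stopifnot(inherits(fit, "nb_pspline"))
  if (any(levels <= 0 | levels >= 1)) {
    stop("levels must lie strictly between 0 and 1", call. = FALSE)
  }
  dm <- strain_d_max(fit, d_max)
  est <- ld_from_coefs(fit$design, fit$coefficients, levels, dm)
  est$d_max <- unname(dm[est$strain])
  est
}

strain_d_max <- function(fit, d_max = NULL) {
  dm <- tapply(fit$data$dose, fit$data$strain, max)
  dm <- stats::setNames(as.numeric(dm), names(dm))
  if (!is.null(d_max)) {
    if (is.null(names(d_max))) {
      dm[] <- rep_len(as.numeric(d_max), length(dm))
    } else {
      dm[names(d_max)] <- as.numeric(d_max)
    }
  }
  dm
}

# internal constructor (also used to inject draws in tests)
new_ld_boot <- function(draws, estimates, n_boot, n_failed, seed, d_max,
                        levels) {
  structure(list(draws = draws, estimates = estimates, n_boot = n_boot,
                 n_failed = n_failed, seed = seed, d_max = d_max,
                 levels = levels),
            class = "ld_boot")
}

#' Parametric bootstrap for lethal-dose uncertainty
#'
#' For each replicate, draws new counts from the fitted negative binomial
#' model at the original design points (NB with mean \eqn{\hat\mu_i} and
#' dispersion \eqn{\hat\theta}), refits the full model — including
#' re-selection of the smoothing parameters and re-estimation of
#' \eqn{\theta}, so the intervals reflect smoothing uncertainty — and
#' records the LDp of every strain at every requested level. Replicates
#' whose refit errors or fails to converge are counted in `n_failed` and
#' excluded from interval computation (with a warning above 5% failures and
#' a hard error above 50%). The draw sequence is fully reproducible from
#' `seed`.
#'
#' If the original fit used fixed `lambda` or fixed `theta`, refits condition
#' on the same fixed values.
#'
#' @param fit A converged `"nb_pspline"` fit.
#' @param levels Survival levels p; default `c(0.5, 0.1)`.
#' @param n_boot Number of bootstrap replicates (>= 2; default 1000).
#' @param seed Integer seed (mandatory).
#' @param d_max Optional per-strain maximum search dose (default: maximum
#'   observed dose per strain). Censored replicate draws enter at `d_max`.
#' @return An object of class `"ld_boot"` holding the per-replicate LD draws
#'   (`tidy()` returns them), the point estimates, `n_boot`, `n_failed` and
#'   the seed.
#' @seealso [ld_confint()], [ld_contrast()]
#' @export
ld_bootstrap <- function(fit, levels = c(0.5, 0.1), n_boot = 1000, seed,
                         d_max = NULL) {
  stopifnot(inherits(fit, "nb_pspline"))
  if (!fit$converged) {
    stop("bootstrap requires a converged fit", call. = FALSE)
  }
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory for bootstrap runs",
                          call. = FALSE)
  if (any(levels <= 0 | levels >= 1)) {
    stop("levels must lie strictly between 0 and 1", call. = FALSE)
  }
  dm <- strain_d_max(fit, d_max)
  estimates <- estimate_ld(fit, levels = levels, d_max = dm)
  design <- fit$design
  st <- fit$settings
  n <- length(fit$y)
  mu <- fit$fitted
  theta <- fit$theta

  cache <- ld_grid_cache(design, dm)
  set.seed(seed)
  draws <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    ystar <- if (theta >= 1e7) stats::rpois(n, mu) else
      stats::rnbinom(n, size = theta, mu = mu)
    refit <- tryCatch({
      if (fit$lambda_fixed) {
        cpp_pnb_fit(design$X, ystar, design$Slist, design$blocks,
                    unname(fit$lambda),
                    if (fit$theta_fixed) theta else 1.0, fit$theta_fixed,
                    st$max_iter, st$tol)
      } else {
        cpp_pnb_select(design$X, ystar, design$Slist, design$blocks,
                       as.numeric(st$lambda_grid), as.integer(st$sweeps),
                       if (fit$theta_fixed) theta else 1.0, fit$theta_fixed,
                       st$max_iter, st$tol)
      }
    }, error = function(e) NULL)
    if (is.null(refit) || !isTRUE(refit$converged)) {
      n_failed <- n_failed + 1L
      next
    }
    beta_b <- drop(refit$coefficients)
    ld_b <- ld_from_coefs(design, beta_b, levels, dm, cache = cache)
    ld_b$replicate <- b
    draws[[b]] <- ld_b
  }
  if (n_failed > n_boot / 2) {
    stop(sprintf("%d of %d bootstrap replicates failed; model too unstable for inference",
                 n_failed, n_boot), call. = FALSE)
  }
  if (n_failed > 0.05 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed to fit", n_failed,
                    n_boot), call. = FALSE)
  }
  draws <- dplyr::bind_rows(draws)[, c("replicate", "strain", "level", "ld",
                                       "censored")]
  new_ld_boot(draws, estimates, n_boot, n_failed, seed, dm, levels)
}

#' @export
print.ld_boot <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: %d replicates (%d failed), seed %s\n",
              x$n_boot, x$n_failed, format(x$seed)))
  print(ld_confint(x))
  invisible(x)
}

#' @export
tidy.ld_boot <- function(x, ...) x$draws

#' Percentile confidence intervals for lethal doses
#'
#' Computes the percentile interval (e.g. 2.5th and 97.5th percentiles for
#' `level = 0.95`) of the successful bootstrap LD draws for every strain and
#' survival level. Censored replicate draws enter the order statistics at
#' the strain's maximum search dose; a bound that lands on such a value is
#' flagged censored.
#'
#' @param boot An `"ld_boot"` object from [ld_bootstrap()].
#' @param level Confidence level (default 0.95).
#' @return Tibble with columns `strain`, `level` (survival level p), `ld`,
#'   `censored`, `ci_low`, `ci_high`, `ci_low_censored`, `ci_high_censored`,
#'   `n_boot`, `n_failed`.
#' @export
ld_confint <- function(boot, level = 0.95) {
  stopifnot(inherits(boot, "ld_boot"))
  alpha <- (1 - level) / 2
  ci <- boot$draws |>
    dplyr::group_by(.data$strain, .data$level) |>
    dplyr::summarise(
      ci_low = stats::quantile(.data$ld, alpha, names = FALSE),
      ci_high = stats::quantile(.data$ld, 1 - alpha, names = FALSE),
      any_censored = any(.data$censored),
      .groups = "drop"
    )
  out <- dplyr::left_join(boot$estimates, ci, by = c("strain", "level"))
  tol <- 1e-9 * pmax(1, out$d_max)
  out$ci_low_censored <- out$any_censored & out$ci_low >= out$d_max - tol
  out$ci_high_censored <- out$any_censored & out$ci_high >= out$d_max - tol
  out$any_censored <- NULL
  out$d_max <- NULL
  out$n_boot <- boot$n_boot
  out$n_failed <- boot$n_failed
  out
}

#' Bootstrap contrast of lethal doses between two strains
#'
#' For each survival level, forms the per-replicate difference
#' LDp(strain_a) - LDp(strain_b) over bootstrap replicates in which both
#' strains' LD values are uncensored, and summarises it by a percentile
#' confidence interval. The difference is declared significant when the
#' interval excludes zero. Replicates censored for at least one strain are
#' excluded from the difference distribution and counted in `n_excluded`.
#'
#' @param boot An `"ld_boot"` object covering both strains.
#' @param strain_a,strain_b Strain identifiers; default the first two strains
#'   in the bootstrap draws.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per survival level: `strain_a`, `strain_b`,
#'   `level` (survival level p), `delta` (point estimate from the original
#'   fit), `ci_low`, `ci_high`, `significant`, `n_excluded`, and a
#'   list-column `deltas` with the replicate differences.
#' @export
ld_contrast <- function(boot, strain_a = NULL, strain_b = NULL,
                        level = 0.95) {
  stopifnot(inherits(boot, "ld_boot"))
  strains <- unique(boot$estimates$strain)
  if (is.null(strain_a)) strain_a <- strains[1]
  if (is.null(strain_b)) strain_b <- strains[2]
  if (is.na(strain_a) || is.na(strain_b) ||
      !all(c(strain_a, strain_b) %in% strains)) {
    stop("both strains must be present in the bootstrap draws",
         call. = FALSE)
  }
  alpha <- (1 - level) / 2
  purrr::map_dfr(boot$levels, function(p) {
    a <- boot$draws[boot$draws$strain == strain_a & boot$draws$level == p, ]
    b <- boot$draws[boot$draws$strain == strain_b & boot$draws$level == p, ]
    m <- dplyr::inner_join(a, b, by = c("replicate", "level"),
                           suffix = c("_a", "_b"))
    ok <- !m$censored_a & !m$censored_b
    deltas <- m$ld_a[ok] - m$ld_b[ok]
    if (length(deltas) < 2) {
      stop("fewer than 2 uncensored replicates for contrast at level ", p,
           call. = FALSE)
    }
    est <- boot$estimates
    pt <- est$ld[est$strain == strain_a & est$level == p] -
      est$ld[est$strain == strain_b & est$level == p]
    lo <- stats::quantile(deltas, alpha, names = FALSE)
    hi <- stats::quantile(deltas, 1 - alpha, names = FALSE)
    tibble::tibble(strain_a = strain_a, strain_b = strain_b, level = p,
                   delta = pt, ci_low = lo, ci_high = hi,
                   significant = lo > 0 | hi < 0,
                   n_excluded = sum(!ok), deltas = list(deltas))
  })
}
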