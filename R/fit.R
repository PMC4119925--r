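#' Fit a penalized-spline negative binomial dose-response model
#'
#' Models colony counts as negative binomial with a log link:
#' \deqn{\log \mu = \beta_0 + \alpha_{strain} + \gamma_{strain:experiment} + f_{strain}(\sqrt{dose})}
#' where each \eqn{f_s} is a P-spline (B-spline basis with a difference
#' penalty) of square-root dose, one smooth per strain, centred to sum to
#' zero over the strain's observed design rows. The square-root transform
#' stabilises estimation on dose grids that span orders of magnitude; the
#' unknown initial inoculum of each assay is absorbed by the intercept and
#' the experiment-within-strain effects, so model-based survival fractions
#' (ratios of predicted means) do not depend on it.
#'
#' Coefficients maximise the penalized NB log-likelihood by iteratively
#' reweighted least squares with step halving (the penalized deviance is
#' non-increasing across iterations), alternating with profile maximum
#' likelihood for the single shared dispersion \eqn{\theta}
#' (variance \eqn{\mu + \mu^2/\theta}; Poisson as \eqn{\theta \to \infty}).
#' Convergence is declared when the relative change in penalized deviance
#' falls below `tol` (default 1e-8), capped at `max_iter` (default 200)
#' iterations. When `lambda` is `NULL`, one smoothing parameter per strain is
#' selected by corrected AIC over a log10 grid (1e-4 to 1e6, 11 points) with
#' coordinate descent across strains (2 sweeps), which is deterministic given
#' the data.
#'
#' Counts are rounded to the nearest integer for the likelihood: c.f.u./mL
#' values are scaled counts and may be non-integral when plate duplicates
#' were averaged upstream.
#'
#' @param data A tolerance tibble (columns `strain`, `experiment`, `dose`,
#'   `count`; see [tolerance_data()]).
#' @param num_basis Basis functions per strain smooth (default 8).
#' @param degree B-spline degree (default 3).
#' @param penalty_order Difference-penalty order (default 2).
#' @param lambda Optional fixed smoothing parameter(s), recycled across
#'   strains or named by strain; `NULL` (default) selects by corrected AIC.
#' @param theta Optional fixed NB dispersion; `NULL` (default) estimates it
#'   by profile maximum likelihood.
#' @param lambda_grid Candidate smoothing grid used when `lambda` is `NULL`.
#' @param sweeps Coordinate-descent sweeps over strains during selection.
#' @param theta_init Starting value for the dispersion estimation
#'   (ignored when `theta` is fixed).
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return An object of class `"nb_pspline"`; see [tidy.nb_pspline()],
#'   [glance.nb_pspline()], [predict.nb_pspline()], [survival_curve()],
#'   [estimate_ld()].
#' @examples
#' sim <- simulate_tolerance(seed = 1)
#' fit <- nb_pspline(sim)
#' glance(fit)
#' @export
nb_pspline <- function(data, num_basis = 8, degree = 3, penalty_order = 2,
                       lambda = NULL, theta = NULL,
                       lambda_grid = 10^seq(-4, 6, by = 1), sweeps = 2,
                       theta_init = 1, max_iter = 200, tol = 1e-8) {
  validate_tolerance(data)
  y <- round(as.numeric(data$count))
  strain <- as.character(data$strain)
  zero_strain <- tapply(y, strain, function(v) all(v == 0))
  if (any(zero_strain)) {
    stop("all counts are zero for strain(s): ",
         paste(names(zero_strain)[zero_strain], collapse = ", "),
         " -- fit is degenerate", call. = FALSE)
  }
  design <- build_design(data, num_basis = num_basis, degree = degree,
                         penalty_order = penalty_order)
  fix_theta <- !is.null(theta)
  theta_init <- if (fix_theta) theta else theta_init
  n_strain <- length(design$strains)

  if (is.null(lambda)) {
    raw <- cpp_pnb_select(design$X, y, design$Slist, design$blocks,
                          as.numeric(lambda_grid), as.integer(sweeps),
                          theta_init, fix_theta, max_iter, tol)
    if (isTRUE(raw$fallback)) {
      warning("smoothing criterion non-finite for all candidates; ",
              "using heaviest smoothing", call. = FALSE)
    }
    lambda_used <- drop(raw$lambda)
  } else {
    lambda_used <- rep_len(as.numeric(lambda), n_strain)
    if (!is.null(names(lambda))) {
      lambda_used <- as.numeric(lambda[design$strains])
    }
    raw <- cpp_pnb_fit(design$X, y, design$Slist, design$blocks,
                       lambda_used, theta_init, fix_theta, max_iter, tol)
  }
  if (!isTRUE(raw$converged)) {
    warning("penalized IRLS did not converge within the iteration cap",
            call. = FALSE)
  }
  beta <- drop(raw$coefficients)
  names(beta) <- design$col_names
  names(lambda_used) <- design$strains
  edf_block <- drop(raw$edf_block)
  names(edf_block) <- design$strains

  structure(list(
    data = tibble::as_tibble(data[, c("strain", "experiment", "dose", "count")]),
    y = y,
    design = design,
    coefficients = beta,
    lambda = lambda_used,
    lambda_fixed = !is.null(lambda),
    theta = raw$theta,
    theta_fixed = fix_theta,
    deviance = raw$deviance,
    loglik = raw$loglik,
    edf = raw$edf,
    edf_by_strain = edf_block,
    fitted = drop(raw$fitted),
    converged = isTRUE(raw$converged),
    iter = raw$iter,
    dev_trace = drop(raw$dev_trace),
    settings = list(num_basis = num_basis, degree = degree,
                    penalty_order = penalty_order,
                    lambda_grid = lambda_grid, sweeps = sweeps,
                    max_iter = max_iter, tol = tol),
    dose_unit = attr(data, "dose_unit"),
    stress = attr(data, "stress")
  ), class = "nb_pspline")
}

#' Read a model configuration YAML
#'
#' Reads optional fitting settings from a YAML file with keys `num_basis`,
#' `degree`, `penalty_order`, `lambda_grid`, `theta_init` (all optional;
#' missing keys take the [nb_pspline()] defaults). The result can be
#' spliced into a fit call with `do.call`.
#'
#' @param path Path to the YAML file.
#' @return Named list of fitting arguments.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("num_basis: 10", "theta_init: 2"), f)
#' cfg <- read_model_config(f)
#' \dontrun{
#' fit <- do.call(nb_pspline, c(list(data), cfg))
#' }
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- c("num_basis", "degree", "penalty_order", "lambda_grid",
               "theta_init")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(num_basis = 8, degree = 3, penalty_order = 2,
                   lambda_grid = 10^seq(-4, 6, by = 1), theta_init = 1)
  utils::modifyList(defaults, lapply(raw, unlist))
}

#' Select smoothing parameters by corrected AIC
#'
#' Convenience wrapper returning only the per-strain smoothing parameters
#' chosen by the corrected-AIC coordinate descent of [nb_pspline()].
#'
#' @inheritParams nb_pspline
#' @return Named numeric vector of smoothing parameters, one per strain.
#' @export
select_smoothing <- function(data, num_basis = 8, degree = 3,
                             penalty_order = 2,
                             lambda_grid = 10^seq(-4, 6, by = 1), sweeps = 2,
                             theta = NULL) {
  fit <- nb_pspline(data, num_basis = num_basis, degree = degree,
                    penalty_order = penalty_order, lambda = NULL,
                    theta = theta, lambda_grid = lambda_grid, sweeps = sweeps)
  fit$lambda
}

#' Predicted mean counts
#'
#' Evaluates the fitted mean c.f.u./mL for given strain, experiment and
#' doses. Within the observed sqrt-dose range the smooth is evaluated
#' exactly; beyond it the linear predictor is extended linearly from the
#' boundary.
#'
#' @param object A fitted `"nb_pspline"` model.
#' @param strain,experiment Identifiers seen during fitting.
#' @param dose Non-negative dose vector (may be empty).
#' @param ... Unused.
#' @return Tibble with columns `strain`, `experiment`, `dose`, `mean`
#'   (strictly positive).
#' @export
predict_mean <- function(object, strain, experiment, dose) {
  stopifnot(inherits(object, "nb_pspline"))
  if (length(dose) == 0) {
    return(tibble::tibble(strain = character(), experiment = character(),
                          dose = numeric(), mean = numeric()))
  }
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  eta0 <- parametric_value(object$design, object$coefficients, strain,
                           experiment)
  f <- smooth_value(object$design, object$coefficients, strain, sqrt(dose))
  tibble::tibble(strain = strain, experiment = experiment, dose = dose,
                 mean = exp(eta0 + f))
}

#' @rdname predict_mean
#' @param newdata Optional data frame with columns `strain`, `experiment`,
#'   `dose`; defaults to the training rows.
#' @export
predict.nb_pspline <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  out <- purrr::pmap_dbl(
    list(as.character(newdata$strain), as.character(newdata$experiment),
         as.numeric(newdata$dose)),
    function(s, e, d) predict_mean(object, s, e, d)$mean
  )
  out
}

#' @export
fitted.nb_pspline <- function(object, ...) object$fitted

#' @export
logLik.nb_pspline <- function(object, ...) {
  structure(object$loglik, df = object$edf + 1, class = "logLik")
}

#' @export
print.nb_pspline <- function(x, ...) {
  cat("Penalized-spline negative binomial dose-response fit\n")
  cat(sprintf("  strains: %s\n", paste(x$design$strains, collapse = ", ")))
  cat(sprintf("  n = %d observations, theta = %.4g%s\n", length(x$y), x$theta,
              if (x$theta_fixed) " (fixed)" else ""))
  cat(sprintf("  lambda: %s\n",
              paste(sprintf("%s=%.3g", names(x$lambda), x$lambda),
                    collapse = ", ")))
  cat(sprintf("  edf = %.2f, deviance = %.2f, converged: %s\n",
              x$edf, x$deviance, x$converged))
  invisible(x)
}

#' Tidy a penalized NB dose-response fit
#'
#' @param x A fitted `"nb_pspline"` model.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`, `type`
#'   (`"parametric"` or `"smooth"`) and `strain` (for smooth terms).
#' @export
tidy.nb_pspline <- function(x, ...) {
  nm <- names(x$coefficients)
  type <- ifelse(startsWith(nm, "s("), "smooth", "parametric")
  strain <- rep(NA_character_, length(nm))
  sm <- type == "smooth"
  strain[sm] <- sub("^s\\((.*)\\)\\.[0-9]+$", "\\1", nm[sm])
  tibble::tibble(term = nm, estimate = unname(x$coefficients),
                 type = type, strain = strain)
}

#' One-row model summary
#'
#' @param x A fitted `"nb_pspline"` model.
#' @param ... Unused.
#' @return Tibble with `nobs`, `edf`, `theta`, `deviance`, `logLik` and
#'   `converged`.
#' @export
glance.nb_pspline <- function(x, ...) {
  tibble::tibble(nobs = length(x$y), edf = x$edf, theta = x$theta,
                 deviance = x$deviance, logLik = x$loglik,
                 converged = x$converged)
}
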