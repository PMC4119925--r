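#' Shoulder-shaped survival curve
#'
#' Ground-truth curve family for simulated tolerance assays. Radiation- and
#' desiccation-resistant bacteria typically show a "shoulder of resistance":
#' survival stays near 1 up to a shoulder dose and then declines
#' exponentially. The family used here is
#' \deqn{\log S(d) = -k\,\mathrm{sp}_s(d - D_0) + k\,\mathrm{sp}_s(-D_0)}
#' where \eqn{\mathrm{sp}_s(x) = s \log(1 + e^{x/s})} is a softplus with
#' transition width `s`, so that S(0) = 1 exactly, S is smooth and strictly
#' decreasing, and in the sharp-transition limit \eqn{s \to 0} it reduces to
#' survival 1 up to \eqn{D_0} followed by exponential decay at rate `k`
#' (pure exponential decay when \eqn{D_0 = 0}). In that limit the true
#' lethal dose has the closed form \eqn{LD_p = D_0 + \log(1/p)/k}.
#'
#' @param dose Non-negative dose vector.
#' @param shoulder Shoulder dose \eqn{D_0 \ge 0}.
#' @param decay_rate Log-survival slope \eqn{k > 0} beyond the shoulder.
#' @param smoothness Transition width \eqn{s > 0}.
#' @return Survival fractions in (0, 1].
#' @export
shoulder_survival <- function(dose, shoulder, decay_rate, smoothness) {
  stopifnot(all(dose >= 0), shoulder >= 0, decay_rate > 0, smoothness > 0)
  sp <- function(x) {
    z <- x / smoothness
    smoothness * (pmax(z, 0) + log1p(exp(-abs(z))))
  }
  exp(-decay_rate * sp(dose - shoulder) + decay_rate * sp(-shoulder))
}

#' True lethal dose of a shoulder curve
#'
#' Numerically inverts [shoulder_survival()] by bisection (relative
#' tolerance 1e-10). Equals \eqn{D_0 + \log(1/p)/k} in the sharp-transition
#' limit.
#'
#' @param p Survival level in (0, 1).
#' @param shoulder,decay_rate,smoothness Curve parameters (see
#'   [shoulder_survival()]).
#' @return The dose at which the true survival equals `p` (vectorised over
#'   `p`).
#' @export
true_ld <- function(p, shoulder, decay_rate, smoothness) {
  if (any(p <= 0 | p >= 1)) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  vapply(p, function(pp) {
    lo <- 0
    hi <- shoulder + log(1 / pp) / decay_rate + 1
    while (shoulder_survival(hi, shoulder, decay_rate, smoothness) > pp) {
      hi <- 2 * hi + 1
    }
    while (hi - lo > 1e-10 * max(hi, 1)) {
      mid <- (lo + hi) / 2
      if (shoulder_survival(mid, shoulder, decay_rate, smoothness) > pp) {
        lo <- mid
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Default dose grids
#'
#' Dose designs typical of microbial stress-tolerance assays: sampling times
#' for chemical stressors (minutes), desiccation sampling days, and a
#' radiation-style dose ladder. A dose-0 (untreated) point is always
#' included.
#'
#' @return Named list of numeric dose grids (`chemical`, `desiccation`,
#'   `radiation`).
#' @export
default_dose_grids <- function() {
  list(chemical = c(0, 1, 5, 10, 20, 40, 60, 120),
       desiccation = c(0, 20, 40, 60, 80, 100),
       radiation = c(0, 2.5, 5, 7.5, 10, 12.5))
}

#' Simulate a stress-tolerance assay
#'
#' Generates colony counts for a multi-strain tolerance experiment with
#' known ground truth. For each strain, experiment and dose (with
#' `plate_replicates` plated aliquots each), counts are drawn from a
#' negative binomial with mean
#' `baseline_count * exp(experiment shift) * S(dose)` and dispersion
#' `theta`, where S is the strain's shoulder survival curve and the
#' experiment shifts are drawn once per (strain, experiment) from
#' Normal(0, `experiment_effect_sd`) on the log scale — multiplicative
#' batch effects matching the log-link fixed effects of the analysis model,
#' and emulating the unknown inoculum of real assays. `theta >= 1e7` is
#' treated as the Poisson limit.
#'
#' The defaults emulate a two-strain assay (test strain and positive
#' control) with two independent experiment repetitions, duplicate plates,
#' an expected untreated count of 1e4 c.f.u./mL and moderate overdispersion.
#'
#' @param strains Data frame with columns `strain`, `shoulder`,
#'   `decay_rate`, `smoothness` (one row per strain), or a named list of
#'   parameter vectors. Default: two strains with shoulders at 2 and 0.5
#'   dose units.
#' @param dose_grid Dose design; default the chemical-stressor grid of
#'   [default_dose_grids()].
#' @param experiments Independent experiment repetitions per strain
#'   (default 2).
#' @param plate_replicates Plated aliquots per experiment and dose
#'   (default 2).
#' @param baseline_count Expected c.f.u./mL at dose 0 (default 1e4).
#' @param experiment_effect_sd SD of the log-scale experiment shifts
#'   (default 0.2).
#' @param theta NB dispersion of the counts (default 5).
#' @param seed Integer seed (mandatory; the dataset is reproducible from
#'   it).
#' @return A tolerance tibble (see [tolerance_data()]) with attribute
#'   `"config"` echoing all parameters and attribute `"truth"`, a tibble of
#'   true LD50/LD10 per strain from [true_ld()].
#' @examples
#' sim <- simulate_tolerance(seed = 42)
#' attr(sim, "truth")
#' @export
simulate_tolerance <- function(strains = NULL,
                               dose_grid = default_dose_grids()$chemical,
                               experiments = 2, plate_replicates = 2,
                               baseline_count = 1e4,
                               experiment_effect_sd = 0.2,
                               theta = 5, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(strains)) {
    strains <- tibble::tibble(
      strain = c("G18", "control"),
      shoulder = c(2, 0.5),
      decay_rate = c(0.08, 0.12),
      smoothness = c(1, 1)
    )
  }
  if (!is.data.frame(strains)) {
    strains <- purrr::imap_dfr(strains, function(par, nm) {
      tibble::tibble(strain = nm, shoulder = par[["shoulder"]],
                     decay_rate = par[["decay_rate"]],
                     smoothness = par[["smoothness"]])
    })
  }
  stopifnot(all(dose_grid >= 0), !is.unsorted(dose_grid),
            experiments >= 1, plate_replicates >= 1, baseline_count > 0,
            experiment_effect_sd >= 0, theta > 0)
  set.seed(seed)
  rows <- vector("list", nrow(strains) * experiments)
  k <- 1
  for (si in seq_len(nrow(strains))) {
    surv <- shoulder_survival(dose_grid, strains$shoulder[si],
                              strains$decay_rate[si],
                              strains$smoothness[si])
    for (e in seq_len(experiments)) {
      shift <- stats::rnorm(1, 0, experiment_effect_sd)
      mu <- rep(baseline_count * exp(shift) * surv, each = plate_replicates)
      counts <- if (theta >= 1e7) stats::rpois(length(mu), mu) else
        stats::rnbinom(length(mu), size = theta, mu = mu)
      rows[[k]] <- tibble::tibble(
        strain = strains$strain[si],
        experiment = paste0("e", e),
        dose = rep(dose_grid, each = plate_replicates),
        count = as.numeric(counts)
      )
      k <- k + 1
    }
  }
  out <- dplyr::bind_rows(rows)
  truth <- purrr::map_dfr(seq_len(nrow(strains)), function(si) {
    tibble::tibble(
      strain = strains$strain[si],
      level = c(0.5, 0.1),
      true_ld = true_ld(c(0.5, 0.1), strains$shoulder[si],
                        strains$decay_rate[si], strains$smoothness[si])
    )
  })
  attr(out, "config") <- list(strains = strains, dose_grid = dose_grid,
                              experiments = experiments,
                              plate_replicates = plate_replicates,
                              baseline_count = baseline_count,
                              experiment_effect_sd = experiment_effect_sd,
                              theta = theta, seed = seed)
  attr(out, "truth") <- truth
  attr(out, "dose_unit") <- "unit"
  attr(out, "stress") <- "simulated"
  out
}
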