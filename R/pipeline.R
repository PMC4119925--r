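#' Run the full lethal-dose analysis
#'
#' End-to-end driver for one stressor and one or two strains: validates the
#' input, fits the penalized NB dose-response model, runs the parametric
#' bootstrap, computes percentile confidence intervals for LD values (and
#' for the between-strain LD difference when exactly two strains are
#' present), builds the two-panel report figure, and optionally writes the
#' whole results bundle to disk:
#'
#' * `ld_estimates.csv` — `strain,stress,level,ld,censored,ci_low,ci_high,n_boot,n_failed`
#' * `ld_contrasts.csv` — `strain_a,strain_b,level,delta,ci_low,ci_high,significant`
#'   (two-strain runs only)
#' * `truth_comparison.csv` — estimates joined with supplied true LD values
#' * `tolerance_figure.<ext>` — the two-panel figure
#' * `manifest.json` — seed, smoothing parameters, dispersion, effective
#'   degrees of freedom, failure counts and any warnings raised during the
#'   run
#'
#' @param data A tolerance tibble or a path to a counts CSV
#'   (see [read_counts_csv()]).
#' @param stress,dose_unit Metadata labels (defaults taken from `data`
#'   attributes when present).
#' @param levels Survival levels p (default `c(0.5, 0.1)`, i.e. LD50 and
#'   LD10).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory).
#' @param out_dir Optional output directory (created if absent); `NULL`
#'   returns the results without writing.
#' @param truth Optional tibble (`strain`, `level`, `true_ld`) or path to a
#'   ground-truth JSON written by the simulator, for a truth-comparison
#'   table.
#' @param plot_scale `"log"` (default) or `"sqrt"` y-axis.
#' @param plot_format `"png"` or `"svg"` (default `"png"`).
#' @param ... Further arguments passed to [nb_pspline()].
#' @return A list of class `"ld_analysis"` with elements `fit`, `boot`,
#'   `estimates`, `contrasts` (`NULL` for one-strain runs), `figure`,
#'   `manifest`.
#' @export
run_ld_analysis <- function(data, stress = NULL, dose_unit = NULL,
                            levels = c(0.5, 0.1), n_boot = 1000, seed,
                            out_dir = NULL, truth = NULL,
                            plot_scale = c("log", "sqrt"),
                            plot_format = c("png", "svg"), ...) {
  plot_scale <- match.arg(plot_scale)
  plot_format <- match.arg(plot_format)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.character(data) && length(data) == 1) {
    data <- read_counts_csv(data,
                            dose_unit = dose_unit %||% NA_character_,
                            stress = stress %||% NA_character_)
  }
  stress <- stress %||% attr(data, "stress") %||% NA_character_
  dose_unit <- dose_unit %||% attr(data, "dose_unit") %||% NA_character_
  validate_tolerance(data)
  strains <- sort(unique(as.character(data$strain)))
  if (length(strains) > 2) {
    stop("unsupported design: more than 2 strains per run (got ",
         length(strains), ")", call. = FALSE)
  }

  run_warnings <- character()
  capture <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      run_warnings <<- c(run_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  fit <- capture(nb_pspline(data, ...))
  boot <- capture(ld_bootstrap(fit, levels = levels, n_boot = n_boot,
                               seed = seed))
  estimates <- ld_confint(boot)
  estimates$stress <- stress
  contrasts <- if (length(strains) == 2) ld_contrast(boot) else NULL
  figure <- plot_tolerance(fit, estimates, contrasts, scale = plot_scale)

  truth_tbl <- NULL
  if (!is.null(truth)) {
    if (is.character(truth)) {
      tj <- jsonlite::read_json(truth, simplifyVector = TRUE)
      truth <- tibble::as_tibble(tj$true_ld)
    }
    truth_tbl <- dplyr::left_join(estimates,
                                  tibble::as_tibble(truth),
                                  by = c("strain", "level")) |>
      dplyr::mutate(error = .data$ld - .data$true_ld,
                    covered = .data$ci_low <= .data$true_ld &
                      .data$true_ld <= .data$ci_high)
  }

  manifest <- list(
    stress = stress, dose_unit = dose_unit, strains = strains,
    levels = levels, n_boot = n_boot, seed = seed,
    lambda = as.list(fit$lambda), theta = fit$theta,
    edf = fit$edf, edf_by_strain = as.list(fit$edf_by_strain),
    converged = fit$converged, n_failed = boot$n_failed,
    warnings = run_warnings
  )

  result <- structure(list(fit = fit, boot = boot, estimates = estimates,
                           contrasts = contrasts, figure = figure,
                           manifest = manifest, truth = truth_tbl),
                      class = "ld_analysis")
  if (!is.null(out_dir)) {
    write_ld_results(result, out_dir, plot_format = plot_format)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis results bundle to disk
#'
#' @param result An `"ld_analysis"` object from [run_ld_analysis()].
#' @param out_dir Output directory (created if absent).
#' @param plot_format `"png"` or `"svg"`.
#' @return `out_dir`, invisibly.
#' @export
write_ld_results <- function(result, out_dir,
                             plot_format = c("png", "svg")) {
  plot_format <- match.arg(plot_format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  est <- result$estimates[, c("strain", "stress", "level", "ld", "censored",
                              "ci_low", "ci_high", "n_boot", "n_failed")]
  readr::write_csv(est, file.path(out_dir, "ld_estimates.csv"))
  if (!is.null(result$contrasts)) {
    ctr <- result$contrasts[, c("strain_a", "strain_b", "level", "delta",
                                "ci_low", "ci_high", "significant")]
    readr::write_csv(ctr, file.path(out_dir, "ld_contrasts.csv"))
  }
  if (!is.null(result$truth)) {
    readr::write_csv(result$truth,
                     file.path(out_dir, "truth_comparison.csv"))
  }
  fig_path <- file.path(out_dir, paste0("tolerance_figure.", plot_format))
  ggplot2::ggsave(fig_path, result$figure, width = 7, height = 7, dpi = 150)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a simulated assay with its ground truth
#'
#' Emits the counts CSV for a simulated dataset together with a JSON file
#' holding the true LD values, the generator configuration and the seed, so
#' a downstream [run_ld_analysis()] call can be scored against the truth.
#'
#' @param sim A simulated tolerance tibble from [simulate_tolerance()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_counts_csv(sim, file.path(out_dir, "counts.csv"))
  cfg <- attr(sim, "config")
  jsonlite::write_json(
    list(true_ld = attr(sim, "truth"),
         config = cfg[setdiff(names(cfg), "strains")],
         strains = cfg$strains,
         seed = cfg$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(out_dir)
}

#' @export
print.ld_analysis <- function(x, ...) {
  cat(sprintf("Lethal-dose analysis (%s, %d bootstrap replicates)\n",
              x$manifest$stress, x$manifest$n_boot))
  print(x$estimates)
  if (!is.null(x$contrasts)) {
    cat("\nStrain contrasts:\n")
    print(dplyr::select(x$contrasts, -"deltas"))
  }
  invisible(x)
}
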