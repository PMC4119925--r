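#' Assemble and validate a tolerance-assay dataset
#'
#' A tolerance dataset is a tidy tibble with one row per plated aliquot:
#' columns `strain`, `experiment` (independent repetition label), `dose`
#' (non-negative, in assay units such as min, days, kGy or mM) and `count`
#' (c.f.u. per mL; real-valued because counts back-calculated from dilution
#' plating are often averages of plate duplicates). Duplicate
#' (strain, experiment, dose) rows are plate replicates and are kept as-is.
#'
#' @param data A data frame with columns `strain`, `experiment`, `dose`,
#'   `count`.
#' @param dose_unit Free-text unit label for the dose axis (e.g. `"min"`).
#' @param stress Free-text stressor name (e.g. `"UV"`, `"mitomycin C"`).
#' @return A tibble with the four canonical columns (original row order
#'   preserved) and attributes `dose_unit` and `stress`.
#' @examples
#' df <- data.frame(strain = "A", experiment = "e1",
#'                  dose = c(0, 5), count = c(200, 20))
#' tolerance_data(df, dose_unit = "min", stress = "UV")
#' @export
tolerance_data <- function(data, dose_unit = NA_character_,
                           stress = NA_character_) {
  validate_tolerance(data)
  out <- tibble::as_tibble(data)[, c("strain", "experiment", "dose", "count")]
  out$strain <- as.character(out$strain)
  out$experiment <- as.character(out$experiment)
  out$dose <- as.numeric(out$dose)
  out$count <- as.numeric(out$count)
  attr(out, "dose_unit") <- dose_unit
  attr(out, "stress") <- stress
  out
}

# Schema and value checks shared by the constructor and the CSV reader.
validate_tolerance <- function(data) {
  required <- c("strain", "experiment", "dose", "count")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dose <- suppressWarnings(as.numeric(data$dose))
  count <- suppressWarnings(as.numeric(data$count))
  bad <- function(x) is.na(x) | !is.finite(x)
  check_rows <- function(flag, what) {
    if (any(flag)) {
      stop(sprintf("invalid %s in row(s) %s", what,
                   paste(which(flag), collapse = ", ")), call. = FALSE)
    }
  }
  check_rows(bad(dose), "dose (must be a finite number)")
  check_rows(bad(count), "count (must be a finite number)")
  check_rows(dose < 0, "dose (must be >= 0)")
  check_rows(count < 0, "count (must be >= 0)")
  strain <- as.character(data$strain)
  experiment <- as.character(data$experiment)
  check_rows(is.na(strain) | !nzchar(strain), "strain (must be non-empty)")
  check_rows(is.na(experiment) | !nzchar(experiment),
             "experiment (must be non-empty)")
  n_dose <- tapply(dose, strain, function(d) length(unique(d)))
  if (any(n_dose < 2)) {
    stop("strain(s) with fewer than 2 distinct doses: ",
         paste(names(n_dose)[n_dose < 2], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a tolerance-assay CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `strain,experiment,dose,count` (extra columns are ignored). Doses and
#' counts are parsed as reals; validation failures name the offending column
#' or row.
#'
#' @param path Path to the CSV file.
#' @param dose_unit,stress Metadata labels attached to the result.
#' @return A validated tolerance tibble (see [tolerance_data()]).
#' @seealso [write_counts_csv()]
#' @export
read_counts_csv <- function(path, dose_unit = NA_character_,
                            stress = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  tolerance_data(raw, dose_unit = dose_unit, stress = stress)
}

#' Write a tolerance-assay CSV
#'
#' Inverse of [read_counts_csv()]: writes the four canonical columns with
#' full numeric precision, preserving row order.
#'
#' @param data A tolerance tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(data, path) {
  validate_tolerance(data)
  out <- data[, c("strain", "experiment", "dose", "count")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed survival fractions
#'
#' For each (strain, experiment) group the survival fraction at dose d is the
#' mean count at d divided by the mean count at the group's minimum tested
#' dose, so the fraction at the minimum dose is exactly 1. The minimum tested
#' dose is used as baseline (rather than requiring dose 0) because some
#' designs, such as desiccation series starting at 20 days, have no untreated
#' sampling point. Fractions are invariant under rescaling all counts in a
#' group by a positive constant, which is what makes them usable when the
#' initial inoculum is unknown.
#'
#' @param data A tolerance tibble.
#' @return A tibble with columns `strain`, `experiment`, `dose`, `fraction`,
#'   one row per distinct dose per group, ordered by strain, experiment, dose.
#' @examples
#' df <- tolerance_data(data.frame(strain = "A", experiment = "e1",
#'                                 dose = c(0, 5), count = c(200, 20)))
#' survival_fractions(df)  # fraction at dose 5 is 0.1
#' @export
survival_fractions <- function(data) {
  validate_tolerance(data)
  means <- data |>
    dplyr::group_by(.data$strain, .data$experiment, .data$dose) |>
    dplyr::summarise(mean_count = mean(.data$count), .groups = "drop_last")
  baseline <- means |>
    dplyr::slice_min(.data$dose, n = 1, with_ties = FALSE) |>
    dplyr::rename(base_dose = "dose", base_count = "mean_count")
  zero_base <- baseline$base_count == 0
  if (any(zero_base)) {
    bad <- baseline[zero_base, ]
    stop("zero mean count at minimum dose for group(s): ",
         paste(paste0(bad$strain, "/", bad$experiment), collapse = ", "),
         " -- survival fractions are undefined", call. = FALSE)
  }
  means |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::ungroup(baseline),
                     by = c("strain", "experiment")) |>
    dplyr::mutate(fraction = .data$mean_count / .data$base_count) |>
    dplyr::select("strain", "experiment", "dose", "fraction") |>
    dplyr::arrange(.data$strain, .data$experiment, .data$dose)
}

#' Read a growth/no-growth MIC table
#'
#' Expects header `strain,agent,concentration_mM,growth` with `growth` coded
#' 0/1.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `strain`, `agent`, `concentration_mM`
#'   (numeric) and `growth` (logical).
#' @examples
#' f <- system.file("extdata", "example_mic_synthetic.csv",
#'                  package = "lethaldose")
#' mic <- read_mic_csv(f)
#' compute_mic(mic, agent = "CuCl2")
#' @export
read_mic_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("strain", "agent", "concentration_mM", "growth")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    strain = as.character(raw$strain),
    agent = as.character(raw$agent),
    concentration_mM = as.numeric(raw$concentration_mM),
    growth = as.logical(as.integer(raw$growth))
  )
}

#' Minimum inhibitory concentration from a growth pattern
#'
#' The MIC is the lowest tested concentration at which no growth is observed,
#' provided growth is also absent at every higher tested concentration. If
#' growth occurs at all tested concentrations the MIC is right-censored at
#' the maximum tested concentration. Non-monotone patterns (growth above a
#' no-growth concentration, which inhibition assays assume away) are resolved
#' conservatively: the smallest concentration above which every call is
#' no-growth is returned, with a warning.
#'
#' @param data A MIC tibble (see [read_mic_csv()]), or any data frame with
#'   columns `concentration_mM` and `growth` (plus `strain`/`agent` for
#'   filtering).
#' @param strain,agent Optional filters when `data` holds several series.
#' @return A one-row tibble with columns `strain`, `agent`, `mic_mM`,
#'   `censored` (`TRUE` when growth persisted at every tested concentration;
#'   `mic_mM` is then the maximum tested concentration, to be read as
#'   MIC > `mic_mM`).
#' @examples
#' tbl <- tibble::tibble(strain = "A", agent = "CuCl2",
#'                       concentration_mM = c(0.1, 0.3, 0.5, 1.0),
#'                       growth = c(TRUE, TRUE, TRUE, FALSE))
#' compute_mic(tbl)  # MIC = 1.0 mM
#' @export
compute_mic <- function(data, strain = NULL, agent = NULL) {
  if (!is.null(strain)) data <- data[data$strain == strain, ]
  if (!is.null(agent)) data <- data[data$agent == agent, ]
  if (nrow(data) == 0) stop("no growth calls for requested series",
                            call. = FALSE)
  conc <- data$concentration_mM
  if (anyDuplicated(conc)) {
    stop("duplicate concentrations in growth series", call. = FALSE)
  }
  o <- order(conc)
  conc <- conc[o]
  growth <- as.logical(data$growth)[o]
  if (any(is.na(growth))) stop("growth calls must be TRUE/FALSE",
                               call. = FALSE)
  k <- length(conc)
  strain_lab <- if (!is.null(data$strain)) data$strain[1] else NA_character_
  agent_lab <- if (!is.null(data$agent)) data$agent[1] else NA_character_
  if (all(growth)) {
    return(tibble::tibble(strain = strain_lab, agent = agent_lab,
                          mic_mM = conc[k], censored = TRUE))
  }
  # index of the last growth call; MIC is the first concentration beyond it
  last_growth <- if (any(growth)) max(which(growth)) else 0L
  monotone <- all(growth[seq_len(last_growth)])
  if (!monotone) {
    warning("non-monotone growth pattern; reporting smallest concentration ",
            "above which all calls are no-growth", call. = FALSE)
  }
  if (last_growth == k) {
    # growth persists at the highest tested concentration: no inhibiting
    # concentration was reached
    return(tibble::tibble(strain = strain_lab, agent = agent_lab,
                          mic_mM = conc[k], censored = TRUE))
  }
  tibble::tibble(strain = strain_lab, agent = agent_lab,
                 mic_mM = conc[last_growth + 1L], censored = FALSE)
}
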