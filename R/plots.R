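#' Dose-response panel: counts, fitted curves and LD markers
#'
#' Upper reporting panel: observed mean c.f.u./mL per strain and dose
#' (points), the fitted mean curve per strain (averaged over that strain's
#' experiment effects), and optional vertical LD50/LD10 markers. The y-axis
#' uses a log10 scale by default or a square-root scale via `scale`.
#'
#' @param object A fitted `"nb_pspline"` model.
#' @param estimates Optional LD tibble from [estimate_ld()] or
#'   [ld_confint()]; adds dashed vertical markers at the LD values.
#' @param scale `"log"` (default) or `"sqrt"` y-axis.
#' @param n_grid Curve resolution (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_pspline <- function(object, estimates = NULL,
                                scale = c("log", "sqrt"), n_grid = 200,
                                ...) {
  scale <- match.arg(scale)
  obs <- object$data |>
    dplyr::group_by(.data$strain, .data$dose) |>
    dplyr::summarise(mean_count = mean(.data$count), .groups = "drop")
  single_dose <- dplyr::n_distinct(object$data$dose) < 2
  curves <- NULL
  if (!single_dose) {
    curves <- purrr::map_dfr(object$design$strains, function(s) {
      dg <- seq(0, max(object$data$dose[object$data$strain == s]),
                length.out = n_grid)
      preds <- purrr::map_dfr(object$design$exp_levels[[s]], function(e) {
        predict_mean(object, s, e, dg)
      })
      preds |>
        dplyr::group_by(.data$strain, .data$dose) |>
        dplyr::summarise(mean_count = mean(.data$mean), .groups = "drop")
    })
  }
  gg <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$dose,
                                          y = .data$mean_count,
                                          colour = .data$strain)) +
    ggplot2::geom_point()
  if (!is.null(curves)) {
    gg <- gg + ggplot2::geom_line(data = curves)
  }
  if (!is.null(estimates) && nrow(estimates) > 0) {
    gg <- gg + ggplot2::geom_vline(
      data = estimates,
      ggplot2::aes(xintercept = .data$ld, colour = .data$strain),
      linetype = "dashed", alpha = 0.6)
  }
  xlab <- if (!is.null(object$dose_unit) && !is.na(object$dose_unit)) {
    paste0("dose (", object$dose_unit, ")")
  } else "dose"
  gg <- gg + ggplot2::labs(x = xlab, y = "mean c.f.u./mL",
                           colour = "strain")
  if (scale == "log") {
    gg <- gg + ggplot2::scale_y_log10()
  } else {
    gg <- gg + ggplot2::scale_y_sqrt()
  }
  gg
}

#' Interval panel: LD values and strain differences
#'
#' Lower reporting panel: horizontal 95% intervals for the LD value of each
#' strain and level, and (when supplied) for the between-strain LD
#' differences, with a dashed vertical reference at zero — a difference
#' interval that excludes zero indicates a significant strain difference.
#'
#' @param estimates LD tibble from [ld_confint()] (needs `ci_low`,
#'   `ci_high`).
#' @param contrasts Optional contrast tibble from [ld_contrast()].
#' @return A ggplot object.
#' @export
plot_ld_intervals <- function(estimates, contrasts = NULL) {
  stopifnot(nrow(estimates) > 0)
  lab_level <- function(p) paste0("LD", round(100 * p))
  est <- tibble::tibble(
    label = paste0(lab_level(estimates$level), " ", estimates$strain),
    value = estimates$ld,
    ci_low = estimates$ci_low,
    ci_high = estimates$ci_high,
    kind = "LD value"
  )
  rows <- est
  if (!is.null(contrasts) && nrow(contrasts) > 0) {
    ctr <- tibble::tibble(
      label = paste0(lab_level(contrasts$level), " ", contrasts$strain_a,
                     " - ", contrasts$strain_b),
      value = contrasts$delta,
      ci_low = contrasts$ci_low,
      ci_high = contrasts$ci_high,
      kind = "difference"
    )
    rows <- dplyr::bind_rows(est, ctr)
  }
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$value, y = .data$label,
                                     colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dose", y = NULL, colour = NULL)
}

#' Two-panel tolerance report figure
#'
#' Combines the dose-response panel ([autoplot.nb_pspline()]) and the LD
#' interval panel ([plot_ld_intervals()]) into the standard two-panel
#' reporting figure.
#'
#' @param fit A fitted `"nb_pspline"` model.
#' @param estimates LD tibble from [ld_confint()].
#' @param contrasts Optional contrast tibble from [ld_contrast()].
#' @param scale `"log"` or `"sqrt"` y-axis for the upper panel.
#' @return A patchwork object (renders as a single figure).
#' @export
plot_tolerance <- function(fit, estimates, contrasts = NULL,
                           scale = c("log", "sqrt")) {
  scale <- match.arg(scale)
  upper <- autoplot.nb_pspline(fit, estimates = estimates, scale = scale)
  lower <- plot_ld_intervals(estimates, contrasts)
  patchwork::wrap_plots(upper, lower, ncol = 1, heights = c(2, 1))
}
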