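#' Plot a mass isotopomer distribution
#'
#' Stacked bars of the (13C, 15N) grid: one bar per 13C count, filled by 15N
#' count.
#'
#' @param mid MID tibble (`n13C`, `n15N`, `fraction`), optionally with
#'   `metabolite` and `time_h` for faceting.
#' @return A ggplot object.
#' @export
plot_mid <- function(mid) {
  p <- ggplot2::ggplot(mid, ggplot2::aes(
    x = factor(.data$n13C), y = .data$fraction,
    fill = factor(.data$n15N)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "13C substitutions", y = "fraction",
      fill = "15N"
    ) +
    ggplot2::theme_minimal()
  if (all(c("metabolite", "time_h") %in% names(mid))) {
    p <- p + ggplot2::facet_grid(metabolite ~ time_h, scales = "free_x")
  }
  p
}

#' Plot percent-labeled time courses per metabolite
#'
#' @param tc Long MID tibble from [simulate_labeling()].
#' @param element `"C"` or `"N"`.
#' @return A ggplot object.
#' @export
plot_labeling_timecourse <- function(tc, element = c("C", "N")) {
  element <- match.arg(element)
  df <- tc |>
    dplyr::group_by(.data$metabolite, .data$time_h) |>
    dplyr::group_modify(function(g, key) {
      n <- if (element == "C") max(g$n13C) else max(g$n15N)
      tibble::tibble(pct = if (n > 0) percent_labeled(g, element, n) else NA_real_)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$pct, colour = .data$metabolite)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (h)",
      y = paste0("atom fraction labeled (", element, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a pooled effect
#'
#' @param object A `pooled_effect` from [pool_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pooled_effect <- function(object, ...) {
  eff <- object$effects
  eff$label <- paste0("study ", seq_len(nrow(eff)))
  zcrit <- stats::qnorm(1 - (1 - object$conf_level) / 2)
  df <- tibble::tibble(
    label = c(eff$label, "pooled"),
    hr = exp(c(eff$log_hr, object$log_hr)),
    lo = exp(c(eff$log_hr - zcrit * eff$se, object$ci_low)),
    hi = exp(c(eff$log_hr + zcrit * eff$se, object$ci_high)),
    pooled = c(rep(FALSE, nrow(eff)), TRUE)
  )
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$label, colour = .data$pooled)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "hazard ratio", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of an integrated meta-analysis
#'
#' @param meta A `meta_result` from [integrate_enzymes()].
#' @param p_cutoff Significance line, default 0.05.
#' @return A ggplot object.
#' @export
plot_volcano <- function(meta, p_cutoff = 0.05) {
  df <- meta$integrated
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$hr), -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log2 integrated HR", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot
#'
#' @param km Result of [km_logrank()].
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km$curves, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival") +
    ggplot2::theme_minimal()
}
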