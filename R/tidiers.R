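#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a constraint curve: one row per metric bin
#'
#' @param x A `constraint_curve`.
#' @param ... Unused.
#' @return Tibble with `context`, `metric`, bin value `x`, `n`, `k`, `p`
#'   and the exclusion flag.
#' @export
tidy.constraint_curve <- function(x, ...) {
  bind_cols(
    tibble(context = x$context %||% NA_character_, metric = x$metric),
    x$bins
  )
}

#' One-row summary of a constraint curve (regression-table shape)
#'
#' @param x A `constraint_curve`.
#' @param ... Unused.
#' @return One-row tibble: context, metric, direction, chosen model,
#'   R-squared and p-value of the chosen model, normalized slope, mean
#'   P(MAF > 0) and sample size.
#' @export
glance.constraint_curve <- function(x, ...) {
  tibble(
    context = x$context %||% NA_character_,
    metric = x$metric,
    direction = x$direction,
    model = x$chosen,
    r2 = if (x$chosen == "quadratic") x$quadratic$pseudo_r2 else x$linear$r2,
    p_value = if (x$chosen == "quadratic") x$quadratic$p_value else x$linear$p_value,
    linear_slope = x$linear$slope,
    linear_r2 = x$linear$r2,
    quadratic_pseudo_r2 = x$quadratic$pseudo_r2,
    normalized_slope = x$normalized_slope,
    mean_p = x$mean_p,
    n = x$n
  )
}

#' Per-variant SPI score table
#'
#' @param x An `spi_fit`.
#' @param ... Unused.
#' @return The per-variant score tibble.
#' @export
tidy.spi_fit <- function(x, ...) {
  x$scores
}

#' Per-context SPI summary
#'
#' @param x An `spi_fit`.
#' @param ... Unused.
#' @return Tibble with per-context variant count, mean P(MAF > 0) and the
#'   AUCs of the active and null model probabilities.
#' @export
glance.spi_fit <- function(x, ...) {
  x$scores |>
    group_by(.data$context) |>
    summarise(
      n = n(),
      p_maf_positive = mean(.data$maf_positive),
      auc_active = auc_rank(.data$p_active, .data$maf_positive),
      auc_null = auc_rank(.data$p_null, .data$maf_positive),
      .groups = "drop"
    )
}

#' Plot a binned constraint curve with its fitted trend
#'
#' Reproduces the familiar depletion plot: per-bin P(MAF > 0) against the
#' structural metric, point size proportional to the number of variants,
#' with the chosen (linear or quadratic) weighted fit overlaid.
#'
#' @param object A `constraint_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.constraint_curve <- function(object, ...) {
  bins <- object$bins[!object$bins$excluded, ]
  fit_fun <- if (object$chosen == "quadratic") {
    co <- object$quadratic$coefficients
    function(x) co[[1]] + co[[2]] * x + co[[3]] * x^2
  } else {
    function(x) object$linear$intercept + object$linear$slope * x
  }
  xs <- seq(min(bins$x), max(bins$x), length.out = 200)
  fit_df <- tibble(x = xs, p = fit_fun(xs))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7,
                        colour = "firebrick") +
    ggplot2::geom_line(data = fit_df, colour = "grey30") +
    ggplot2::labs(
      x = object$metric,
      y = "P(MAF > 0)",
      title = paste0("Constraint on ", object$metric,
                     if (!is.null(object$context))
                       paste0(" (", object$context, ")")),
      size = "variants"
    ) +
    ggplot2::theme_minimal()
}

#' Binned P(MAF > 0) against a Phred-scaled score
#'
#' Groups variants by integer score bins and plots the per-bin proportion
#' with MAF > 0, with the global average as a reference line — the standard
#' way to visualise whether a score captures population constraint.
#'
#' @param data Tibble with the score column and logical `maf_positive`.
#' @param score Score column name (e.g. `"spi_phred"` or `"surf"`).
#' @param min_bin_n Bins with fewer variants are dropped.
#' @return A ggplot object.
#' @export
plot_score_constraint <- function(data, score, min_bin_n = 50) {
  stopifnot(score %in% names(data), "maf_positive" %in% names(data))
  binned <- data |>
    mutate(bin = floor(.data[[score]])) |>
    group_by(.data$bin) |>
    summarise(n = n(), p = mean(.data$maf_positive), .groups = "drop") |>
    filter(.data$n >= min_bin_n)
  global_p <- mean(data$maf_positive)
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$p)) +
    ggplot2::geom_hline(yintercept = global_p, colour = "grey50",
                        linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "firebrick",
                        alpha = 0.8) +
    ggplot2::geom_line(colour = "firebrick", alpha = 0.5) +
    ggplot2::labs(x = paste0(score, " (binned)"), y = "P(MAF > 0)",
                  size = "variants") +
    ggplot2::theme_minimal()
}
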