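# ggplot2 views of the result objects. All return a ggplot so callers can
# re-theme or add layers.

#' Volcano panels of an allelic-series fit
#'
#' One panel per deletion step: coefficient against -log10 adjusted p,
#' significant proteins highlighted.
#'
#' @param object An `allelic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot allelic_fit
#' @export
autoplot.allelic_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[is.finite(td$estimate) & is.finite(td$p.adjusted), ]
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$estimate,
    y = -log10(pmax(.data$p.adjusted, .Machine$double.xmin)),
    colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~step, nrow = 1) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      na.value = "grey80"
    ) +
    ggplot2::labs(
      x = expression(beta ~ "(log2 step effect)"),
      y = expression(-log[10] ~ "adjusted" ~ italic(p)),
      colour = "adj. p < 0.05"
    ) +
    ggplot2::theme_bw()
}

#' Empirical CDFs of step coefficients by compartment
#'
#' Mirrors the distribution-level comparison of a protein group against
#' the full quantified background: ECDFs of one step's coefficients for
#' each ER class, with the whole background in black.
#'
#' @param fit An `allelic_fit`.
#' @param annotations Annotation tibble with `protein_id` and `er_class`.
#' @param step Step index or label.
#' @return A ggplot.
#' @export
plot_beta_ecdf <- function(fit, annotations, step = 1L) {
  stopifnot(inherits(fit, "allelic_fit"))
  if (is.character(step)) step <- match(step, fit$steps)
  td <- tibble::tibble(
    protein_id = fit$protein_id,
    estimate = fit$beta[, step]
  )
  td <- dplyr::left_join(
    td, annotations[, c("protein_id", "er_class")], by = "protein_id"
  )
  td$er_class[is.na(td$er_class)] <- "none"
  background <- dplyr::mutate(td, er_class = "all quantified")
  ggplot2::ggplot(
    dplyr::bind_rows(td[td$er_class != "none", ], background),
    ggplot2::aes(x = .data$estimate, colour = .data$er_class)
  ) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(
      x = bquote(beta ~ "(" * .(fit$steps[step]) * ", log2)"),
      y = "cumulative fraction",
      colour = NULL
    ) +
    ggplot2::theme_bw()
}

#' Waterfall plot of ranked accumulated and depleted proteins
#'
#' @param ranked Output of [rank_top()].
#' @return A ggplot.
#' @export
plot_rank_top <- function(ranked) {
  check_columns(ranked, c("label", "value", "direction"), "ranked")
  ranked$label <- factor(ranked$label, levels = rev(ranked$label))
  ggplot2::ggplot(ranked, ggplot2::aes(
    x = .data$value, y = .data$label, fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(top = "firebrick", bottom = "steelblue")
    ) +
    ggplot2::labs(x = "coefficient (log2)", y = NULL, fill = NULL) +
    ggplot2::theme_bw()
}

#' Histogram of randomized-selection KS p-values
#'
#' @param object A `ks_null`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ks_null
#' @export
autoplot.ks_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$p.value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "two-sided KS p-value per randomized selection",
      y = "iterations",
      title = paste0(object$group_label, ": median p = ",
                     signif(object$median_p, 3))
    ) +
    ggplot2::theme_bw()
}

#' Bar chart of BAFA-normalized Keima flux ratios
#'
#' @param flux Tibble from [normalize_to_bafa()].
#' @return A ggplot.
#' @export
plot_flux <- function(flux) {
  check_columns(flux, c("condition", "normalized_ratio"), "flux")
  ggplot2::ggplot(flux, ggplot2::aes(
    x = .data$condition, y = .data$normalized_ratio
  )) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(
      x = NULL,
      y = "acidic/neutral Keima ratio (BAFA-normalized)"
    ) +
    ggplot2::theme_bw()
}
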