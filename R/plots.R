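# ggplot2 views of the analysis objects.

#' Bar chart of behaviour frequencies
#'
#' Record counts of the five analysed behaviours per species and combined.
#'
#' @param data A validated scan-record tibble (or the output of
#'   [behaviour_frequencies()]).
#' @return A ggplot object.
#' @export
plot_behaviour_frequencies <- function(data) {
  freq <- if (all(c("behaviour", "n", "proportion") %in% names(data))) {
    data
  } else {
    behaviour_frequencies(data)
  }
  freq |>
    dplyr::mutate(
      behaviour = factor(.data$behaviour, levels = analysed_behaviours())
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$behaviour, y = .data$n,
                                 fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "behaviour", y = "records", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.null_distribution <- function(object, bins = 30, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::labs(
      x = "null statistic", y = "iterations",
      title = paste0("Randomization null (", object$scheme, ", ",
                     object$n_iterations, " iterations)")
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$observed)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed,
                                 linetype = "dashed")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.synchrony_test <- function(object, bins = 30, ...) {
  autoplot(object$null, bins = bins, ...) +
    ggplot2::labs(
      title = paste0("Within-species synchrony null (", object$species, ")"),
      subtitle = paste0(
        "observed mean BS = ", signif(object$observed_mean, 3),
        ", p (", object$direction, ") = ",
        format.pval(object$p_value, eps = 1e-4)
      )
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.crosscorr_matrix <- function(object, ...) {
  object |>
    dplyr::mutate(
      capuchin_behaviour = factor(.data$capuchin_behaviour,
                                  levels = analysed_behaviours()),
      squirrel_behaviour = factor(.data$squirrel_behaviour,
                                  levels = rev(analysed_behaviours()))
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$capuchin_behaviour,
                                 y = .data$squirrel_behaviour,
                                 fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$r), "n/a",
                                                   sprintf("%.2f", .data$r)))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = "capuchin behaviour", y = "squirrel-monkey behaviour",
                  fill = "r") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.crosscorr_null <- function(object, bins = 30, ...) {
  obs <- tibble::tibble(
    behaviour = names(object$observed),
    r = unname(object$observed)
  )
  tidy(object, draws = TRUE) |>
    dplyr::filter(!is.na(.data$r)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = obs[!is.na(obs$r), ],
                        ggplot2::aes(xintercept = .data$r),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~behaviour) +
    ggplot2::labs(
      x = "cross-correlation (r)", y = "iterations",
      title = "Shuffle-split null vs observed same-behaviour correlations"
    ) +
    ggplot2::theme_minimal()
}
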