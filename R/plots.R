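#' Reliability diagram for an evaluation
#'
#' Occupied bins are drawn as points (sized by bin occupancy) against the
#' diagonal of perfect calibration.
#'
#' @param object A `soz_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot soz_eval
#' @export
autoplot.soz_eval <- function(object, ...) {
  df <- filter(object$calibration, n > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = conf, y = f_pos)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = n), colour = "#2166ac") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean stated likelihood (bin)", y = "Fraction correct (bin)",
      size = "Entries",
      title = sprintf("Reliability (Brier = %.4f)", object$brier)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ablation result
#'
#' Length axis: per-bin mean score with standard-error bars. Persona and
#' language axes: per-level scores with deltas against the baseline level.
#'
#' @param object A `soz_ablation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot soz_ablation
#' @export
autoplot.soz_ablation <- function(object, ...) {
  lv <- object$levels
  if (object$axis == "length") {
    lv$level <- factor(lv$level, levels = lv$level)
    return(
      ggplot2::ggplot(lv, ggplot2::aes(x = level, y = score, group = 1)) +
        ggplot2::geom_line(colour = "#b2182b") +
        ggplot2::geom_pointrange(
          ggplot2::aes(ymin = score - sem, ymax = score + sem),
          colour = "#b2182b"
        ) +
        ggplot2::labs(
          x = "Description length (words)", y = "Mean score",
          title = sprintf(
            "Length effect (Kruskal-Wallis p = %.3g, KS vs shuffled p = %.3g)",
            object$tests$kruskal_p, object$tests$ks_p
          )
        ) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
    )
  }
  if (object$axis == "language") {
    return(
      ggplot2::ggplot(lv, ggplot2::aes(x = language, y = f1, fill = condition)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(x = "Language", y = "Weighted F1", fill = "Condition") +
        ggplot2::theme_minimal()
    )
  }
  lv$level <- factor(lv$level, levels = lv$level)
  ggplot2::ggplot(lv, ggplot2::aes(x = level, y = delta_f1)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = NULL, y = sprintf("Delta weighted F1 vs %s", object$baseline)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Strategy comparison for a grid run
#'
#' Weighted F1 (with its bootstrap interval) per prompt strategy.
#'
#' @param object A `soz_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot soz_grid
#' @export
autoplot.soz_grid <- function(object, ...) {
  df <- glance(object)
  df$strategy <- factor(df$strategy, levels = df$strategy)
  ggplot2::ggplot(df, ggplot2::aes(x = strategy, y = f1)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = f1_lower, ymax = f1_upper)) +
    ggplot2::labs(x = "Prompt strategy", y = "Weighted F1") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
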