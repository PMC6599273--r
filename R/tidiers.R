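## broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted growth model
#'
#' One row per model term with estimate, standard error, Wald p-value and
#' odds ratio.
#'
#' @param x a `growth_model`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.growth_model <- function(x, ...) {
  dplyr::mutate(x$coefficients, family_tag = x$family_tag)
}

#' @rdname tidy.growth_model
#' @export
glance.growth_model <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    family_tag = x$family_tag,
    n = nrow(x$data),
    n_covariates = length(x$covariates),
    null_deviance = f$null.deviance,
    deviance = f$deviance,
    aic = stats::AIC(f),
    separation = x$separation
  )
}

#' Tidy a selection report
#'
#' One row per candidate feature with its per-stage statistics and the
#' stage at which it was dropped (`NA` for final survivors).
#'
#' @param x a `selection_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.selection_report <- function(x, ...) {
  tt <- dplyr::select(x$ttest, "feature", "p_value")
  au <- dplyr::select(x$auroc, "feature", "mean_auroc")
  pr <- dplyr::select(x$pruning, "feature", "component")
  out <- dplyr::left_join(tt, au, by = "feature")
  out <- dplyr::left_join(out, pr, by = "feature")
  out$dropped_at <- dplyr::case_when(
    out$feature %in% x$survivors$final ~ NA_character_,
    out$feature %in% x$survivors$pruning ~ "backward_elimination",
    out$feature %in% x$survivors$auroc ~ "correlation_pruning",
    out$feature %in% x$survivors$ttest ~ "bootstrap_auroc",
    TRUE ~ "ttest"
  )
  out
}

#' @rdname tidy.selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$ttest),
    n_after_ttest = length(x$survivors$ttest),
    n_after_auroc = length(x$survivors$auroc),
    n_after_pruning = length(x$survivors$pruning),
    n_final = length(x$survivors$final),
    separation = x$separation
  )
}

#' ROC curve plot for a fitted growth model
#'
#' @param object a `growth_model`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.growth_model <- function(object, ...) {
  pts <- roc_points(as.numeric(stats::fitted(object$fit)), object$data$.y)
  a <- auroc(stats::fitted(object$fit), object$data$.y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s model ROC (AUROC %.3f)", object$family_tag, a),
      x = "1 - specificity", y = "sensitivity"
    ) +
    ggplot2::theme_minimal()
}

#' Nomogram plot
#'
#' Draws the per-covariate point scales and the total-points to predicted
#' probability axis.
#'
#' @param object a `nomogram_spec`.
#' @param n_prob_ticks probability tick marks on the risk axis.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nomogram_spec <- function(object, n_prob_ticks = 7, ...) {
  sc <- object$scales
  rows <- purrr::map_dfr(seq_len(nrow(sc)), function(i) {
    r <- sc[i, ]
    x <- seq(r$lo, r$hi, length.out = 5)
    tibble::tibble(axis = r$term, y = -i,
                   points = object$points_for(r$term, x),
                   lab = format(signif(x, 3)))
  })
  total_max <- sum(sc$max_points)
  probs <- stats::plogis(object$lp_offset +
                           seq(0, total_max, length.out = n_prob_ticks) / object$points_per_unit)
  risk <- tibble::tibble(
    axis = "risk", y = -(nrow(sc) + 1.5),
    points = seq(0, total_max, length.out = n_prob_ticks) * 100 / max(total_max, 1e-9),
    lab = sprintf("%.2f", probs)
  )
  risk$points <- seq(0, 100, length.out = n_prob_ticks)
  all_rows <- dplyr::bind_rows(rows, risk)
  ggplot2::ggplot(all_rows, ggplot2::aes(x = .data$points, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$axis), colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), vjust = -0.9, size = 2.8) +
    ggplot2::geom_text(
      data = dplyr::distinct(all_rows, .data$axis, .data$y),
      ggplot2::aes(x = -8, label = .data$axis), hjust = 1, size = 3
    ) +
    ggplot2::scale_x_continuous(limits = c(-40, 105), breaks = seq(0, 100, 20)) +
    ggplot2::labs(title = sprintf("Nomogram: %s", object$model_tag),
                  x = "points", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}

#' Growth-pattern plot for a cohort
#'
#' Per-interval VDT against interval index, coloured by class, with the
#' 400-day rule drawn.
#'
#' @param growth a tibble from [growth_table()].
#' @return A ggplot.
#' @export
plot_growth <- function(growth) {
  g <- dplyr::mutate(growth,
                     vdt_plot = pmin(pmax(.data$vdt, -2000), 6000))
  ggplot2::ggplot(g, ggplot2::aes(x = factor(.data$interval), y = .data$vdt_plot,
                                  colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 400, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = "screening interval", y = "VDT (days, clipped)",
                  colour = "growth class") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
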