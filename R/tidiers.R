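#' Tidy a fitted radiomics Cox model
#'
#' @param x a `radiomics_cox_model`.
#' @param ... unused.
#' @return Tibble with one row per selected feature: `term`, `estimate`
#'   (log hazard ratio per SD of the feature), `std.error`, `statistic`,
#'   `p.value` (`NA` for a ridge-penalised fallback fit).
#' @export
tidy.radiomics_cox_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    tibble(term = x$features,
           estimate = unname(x$coefficients),
           std.error = unname(sm[, "se(coef)"]),
           statistic = unname(sm[, "z"]),
           p.value = unname(sm[, "Pr(>|z|)"]))
  } else {
    tibble(term = x$features, estimate = unname(x$coefficients),
           std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
  }
}

#' Glance at a fitted radiomics Cox model
#'
#' @param x a `radiomics_cox_model`.
#' @param ... unused.
#' @return One-row tibble: `n`, `n_event`, `n_features`, `lambda` (the
#'   LASSO penalty used for selection, if any), `cutoff`, `penalized`.
#' @export
glance.radiomics_cox_model <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, n_features = length(x$features),
         lambda = x$lambda, cutoff = x$cutoff, penalized = x$penalized)
}

#' @describeIn tidy.radiomics_cox_model forest-style coefficient plot.
#' @param object a `radiomics_cox_model`.
#' @export
autoplot.radiomics_cox_model <- function(object, ...) {
  df <- tidy(object)
  df$lo <- df$estimate - 1.96 * df$std.error
  df$hi <- df$estimate + 1.96 * df$std.error
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15, na.rm = TRUE) +
    ggplot2::labs(x = "log hazard ratio per SD", y = NULL) +
    ggplot2::theme_minimal()
}
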