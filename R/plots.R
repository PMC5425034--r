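# ggplot2 methods for the result classes.

#' Plot posterior densities of the adjusted parameter samples
#'
#' One weighted density panel per parameter, with the weighted median and
#' 90% credible bounds marked.
#'
#' @param object An `abc_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abc_posterior <- function(object, ...) {
  pars <- object$summary$parameter
  long <- tidyr::pivot_longer(
    object$samples[, c(pars, "weight")],
    cols = dplyr::all_of(pars),
    names_to = "parameter", values_to = "value"
  )
  summ <- object$summary
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     weight = .data$weight)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(data = summ,
                        ggplot2::aes(xintercept = .data$median),
                        linetype = 1) +
    ggplot2::geom_vline(data = summ, ggplot2::aes(xintercept = .data$q050),
                        linetype = 3) +
    ggplot2::geom_vline(data = summ, ggplot2::aes(xintercept = .data$q950),
                        linetype = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density")
}

#' Plot scenario posterior probabilities
#'
#' Direct (retained-set proportion) and logistic-regression estimates side
#' by side, with bootstrap intervals when present.
#'
#' @param object An `abc_model_choice`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abc_model_choice <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("scenario", "prob_direct",
                                  "prob_logistic")],
    cols = c("prob_direct", "prob_logistic"),
    names_to = "method", values_to = "probability"
  )
  long$method <- sub("prob_", "", long$method)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$scenario),
                                          y = .data$probability,
                                          fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "scenario", y = "posterior probability")
  if ("ci_low" %in% names(object)) {
    ci <- tibble::as_tibble(object)
    p <- p + ggplot2::geom_errorbar(
      data = ci,
      ggplot2::aes(x = factor(.data$scenario), ymin = .data$ci_low,
                   ymax = .data$ci_high),
      inherit.aes = FALSE, width = 0.2
    )
  }
  p
}

#' Plot the PCA pre-evaluation
#'
#' Simulated reference-table points on the first two principal components,
#' coloured by scenario, with the observed data as a black star.
#'
#' @param object An `abc_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abc_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$scenario))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_point(data = object$observed,
                        ggplot2::aes(x = .data$PC1, y = .data$PC2),
                        inherit.aes = FALSE, shape = 8, size = 4) +
    ggplot2::labs(
      colour = "scenario",
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2])
    )
}

#' Plot the posterior predictive model check
#'
#' Observed statistics against their posterior predictive tail
#' probabilities; points below the Bonferroni line flag misfit.
#'
#' @param object An `abc_model_check`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abc_model_check <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  thr <- alpha / nrow(object)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$statistic, y = .data$p_value,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "tail probability")
}
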