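# ggplot2 displays for the posterior summary types.

#' Plot a root-split posterior
#'
#' Horizontal bar chart of posterior root-split probabilities, most
#' supported split on top.
#'
#' @param object A [root_split_posterior()] tibble.
#' @param max_splits Show at most this many splits (default 12).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.root_split_posterior <- function(object, max_splits = 12, ...) {
  df <- utils::head(object, max_splits)
  df$split <- factor(df$split, levels = rev(df$split))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$split)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "posterior probability", y = NULL,
                  title = "Posterior over root splits") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a standardized marginal likelihood curve
#'
#' The posterior/prior density ratio against the parameter value; the
#' horizontal line at 1 marks "no evidence either way", and a curve
#' dropping to ~0 at the origin is evidence against the parameter being 0.
#'
#' @param object An [standardized_marginal_likelihood()] tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sml_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = expression(sigma),
                  y = "posterior density / prior density",
                  title = "Standardized marginal likelihood") +
    ggplot2::theme_minimal()
}

#' Trace plot of an MCMC fit
#'
#' Log-likelihood (and log-prior) against iteration for the retained
#' samples — the basic mixing diagnostic.
#'
#' @param object A `root_mcmc` fit.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.root_mcmc <- function(object, ...) {
  df <- object$trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$log_likelihood)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "iteration", y = "log-likelihood",
                  title = paste0("Trace (", object$model, " model)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
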