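# broom-style tidiers for MCMC fits.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of the scalar parameters
#'
#' Posterior mean, sd and central credible interval for each scalar
#' parameter in the trace (NR: `kappa`, `alpha`, `sigma_r`, `sigma_n`, the
#' four `pi` components; HB: `s`, `alpha`, root GC).
#'
#' @param x A `root_mcmc` fit.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Ignored.
#' @return Tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior sd), `conf.low`, `conf.high`.
#' @export
tidy.root_mcmc <- function(x, conf_level = 0.95, ...) {
  tr <- x$trace
  skip <- c("iteration", "root_split")
  terms <- setdiff(names(tr), skip)
  a <- (1 - conf_level) / 2
  rows <- lapply(terms, function(tm) {
    v <- tr[[tm]]
    tibble::tibble(term = tm, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = unname(stats::quantile(v, a)),
                   conf.high = unname(stats::quantile(v, 1 - a)))
  })
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x A `root_mcmc` fit.
#' @param ... Ignored.
#' @return Tibble with model, problem size, chain settings, mean
#'   log-likelihood, the effective sample size of the log-likelihood trace
#'   and the overall acceptance rate.
#' @export
glance.root_mcmc <- function(x, ...) {
  acc <- sum(x$acceptance$accepted) / max(1, sum(x$acceptance$proposed))
  tibble::tibble(model = x$model, n_taxa = length(x$labels),
                 n_sites = x$n_sites, n_iter = x$options$n_iter,
                 n_retained = length(x$samples),
                 mean_log_likelihood = mean(x$trace$log_likelihood),
                 ess_log_likelihood = ess(x$trace$log_likelihood),
                 acceptance_rate = acc)
}

# Effective sample size by the initial-positive-sequence estimator on the
# autocorrelation function.
ess <- function(v) {
  n <- length(v)
  if (n < 10 || stats::sd(v) == 0) return(as.numeric(n))
  ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1L] - 1L)]
  max(1, n / (1 + 2 * sum(ac)))
}
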