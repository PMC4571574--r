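# Prior specification, joint log-prior density, and exact prior draws.

#' Prior specification
#'
#' Hyperparameters of the Bayesian hierarchical priors for both models.
#' Defaults:
#' NR — `pi ~ Dirichlet(1,1,1,1)`; `log kappa ~ Normal(0, 1)`;
#' `eps_r | sigma_r ~ iid Normal(0, sigma_r^2)` (6);
#' `eps_n | sigma_n ~ iid Normal(0, sigma_n^2)` (12);
#' `sigma_r, sigma_n ~ Exponential(mean 0.25)`; `alpha ~ Exponential(mean 1)`.
#' HB — `rho`: 6 iid Exponential(mean 1), then mean-normalized; compositions
#' in additive-log-ratio coordinates
#' `a = (log pi_A/pi_T, log pi_C/pi_T, log pi_G/pi_T)`:
#' `a_root ~ Normal(0, 5^2 I_3)`, and for each branch `b` not adjacent to the
#' root, `a_b | a_parent(b) ~ Normal(a_parent(b), s^2 I_3)` where `parent(b)`
#' is the adjacent branch on the root side (root-adjacent branches carry
#' `a_root`); `s ~ Exponential(mean 0.5)`.  Both models: branch lengths iid
#' `Exponential(mean 0.1)` and a uniform prior over rooted binary topologies.
#'
#' @param sigma_r_mean,sigma_n_mean Exponential prior means for the NR
#'   perturbation scales.
#' @param log_kappa_mean,log_kappa_sd Normal prior on `log kappa`.
#' @param alpha_mean Exponential prior mean for the gamma shape.
#' @param s_mean Exponential prior mean for the HB composition-drift sd.
#' @param a_root_sd Normal sd of the root composition's alr coordinates.
#' @param rho_mean Exponential mean of the raw HB exchangeabilities.
#' @param brlen_mean Exponential prior mean for branch lengths
#'   (substitutions/site).
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(sigma_r_mean = 0.25, sigma_n_mean = 0.25,
                       log_kappa_mean = 0, log_kappa_sd = 1,
                       alpha_mean = 1, s_mean = 0.5, a_root_sd = 5,
                       rho_mean = 1, brlen_mean = 0.1) {
  vals <- list(sigma_r_mean = sigma_r_mean, sigma_n_mean = sigma_n_mean,
               log_kappa_mean = log_kappa_mean, log_kappa_sd = log_kappa_sd,
               alpha_mean = alpha_mean, s_mean = s_mean,
               a_root_sd = a_root_sd, rho_mean = rho_mean,
               brlen_mean = brlen_mean)
  if (any(!vapply(vals, function(x) is.finite(x) && x > 0, TRUE) &
          names(vals) != "log_kappa_mean"))
    stop("all prior hyperparameters except log_kappa_mean must be positive")
  structure(vals, class = "prior_spec")
}

## --- alr transform --------------------------------------------------------

# a = (log pi_A/pi_T, log pi_C/pi_T, log pi_G/pi_T)
alr <- function(pi) log(pi[1:3] / pi[4])
alr_inv <- function(a) { e <- c(exp(a), 1); e / sum(e) }
# log |da/dpi| for the alr bijection between the 3-simplex and R^3
alr_log_jacobian <- function(pi) -sum(log(pi))

dnorm3 <- function(x, mean, sd) sum(stats::dnorm(x, mean, sd, log = TRUE))

## --- joint log prior ------------------------------------------------------

#' Joint log-prior density
#'
#' The joint prior of model parameters, branch lengths and topology under
#' [prior_spec()].  Densities are with respect to Lebesgue measure on the
#' natural scales (`kappa`, `sigma`, `alpha`, `s`, branch lengths positive
#' reals; compositions on the 3-simplex, with the alr Jacobians included;
#' the mean-normalized HB exchangeabilities contribute their uniform
#' Dirichlet-derived constant).  States outside the support return `-Inf`.
#'
#' @param params [nr_parameters()] or [hb_parameters()].
#' @param tree Rooted binary `phylo` (branch lengths enter the prior; for HB
#'   it also fixes the composition hierarchy).
#' @param prior A [prior_spec()].
#' @return Log prior density (scalar, possibly `-Inf`).
#' @export
log_prior <- function(params, tree, prior = prior_spec()) {
  tr <- rt_from_phylo(tree, check_lengths = FALSE)
  el <- tr$elen[-tr$root]
  if (any(el <= 0)) return(-Inf)
  lp_len <- sum(stats::dexp(el, rate = 1 / prior$brlen_mean, log = TRUE))
  if (inherits(params, "nr_parameters")) {
    if (params$kappa <= 0 || params$alpha <= 0) return(-Inf)
    if (params$sigma_r < 0 || params$sigma_n < 0) return(-Inf)
    lp_eps_r <- if (params$sigma_r == 0) {
      if (any(params$eps_r != 0)) -Inf else 0
    } else sum(stats::dnorm(params$eps_r, 0, params$sigma_r, log = TRUE))
    lp_eps_n <- if (params$sigma_n == 0) {
      if (any(params$eps_n != 0)) -Inf else 0
    } else sum(stats::dnorm(params$eps_n, 0, params$sigma_n, log = TRUE))
    lgamma(4) +  # Dirichlet(1,1,1,1) on pi
      stats::dnorm(log(params$kappa), prior$log_kappa_mean,
                   prior$log_kappa_sd, log = TRUE) - log(params$kappa) +
      lp_eps_r + lp_eps_n +
      stats::dexp(params$sigma_r, 1 / prior$sigma_r_mean, log = TRUE) +
      stats::dexp(params$sigma_n, 1 / prior$sigma_n_mean, log = TRUE) +
      stats::dexp(params$alpha, 1 / prior$alpha_mean, log = TRUE) +
      lp_len
  } else if (inherits(params, "hb_parameters")) {
    if (params$s <= 0 || params$alpha <= 0) return(-Inf)
    keys <- rt_clade_keys(tr)
    a_root <- alr(params$pi_root)
    lp_comp <- dnorm3(a_root, 0, prior$a_root_sd) +
      alr_log_jacobian(params$pi_root)
    root_kids <- c(tr$kid1[tr$root], tr$kid2[tr$root])
    for (v in setdiff(seq_len(rt_nnode_total(tr)), c(tr$root, root_kids))) {
      a_v <- alr(params$pi_branch[[keys[v]]])
      p <- tr$par[v]
      a_par <- if (p %in% root_kids) a_root
               else alr(params$pi_branch[[keys[p]]])
      lp_comp <- lp_comp + dnorm3(a_v, a_par, params$s) +
        alr_log_jacobian(params$pi_branch[[keys[v]]])
    }
    # mean-normalized iid Exponentials are uniform on {rho > 0, mean(rho)=1}
    lp_rho <- lgamma(6) - 5 * log(6)
    lp_rho + lp_comp +
      stats::dexp(params$s, 1 / prior$s_mean, log = TRUE) +
      stats::dexp(params$alpha, 1 / prior$alpha_mean, log = TRUE) +
      lp_len
  } else stop("params must be nr_parameters or hb_parameters")
}

## --- prior draws ----------------------------------------------------------

#' Draw model parameters from the prior
#'
#' An exact draw from the [prior_spec()] prior, including the HB
#' tree-autocorrelated composition walk (root to tips along the branch
#' hierarchy).  Used for prior-recovery testing, calibration checks and
#' chain initialization.
#'
#' @param tree Rooted binary `phylo` (fixes the HB hierarchy).
#' @param model `"NR"` or `"HB"`.
#' @param prior A [prior_spec()].
#' @param K Gamma category count to record in the parameter block.
#' @param sigma_r,sigma_n,s Optionally fix a hyperparameter instead of
#'   drawing it (e.g. `s = 1e-9` makes all branch compositions collapse to
#'   the root composition).
#' @return [nr_parameters()] or [hb_parameters()].
#' @export
draw_parameters_from_prior <- function(tree, model = c("NR", "HB"),
                                       prior = prior_spec(), K = 4,
                                       sigma_r = NULL, sigma_n = NULL,
                                       s = NULL) {
  model <- match.arg(model)
  tr <- rt_from_phylo(tree)
  alpha <- stats::rexp(1, 1 / prior$alpha_mean)
  if (model == "NR") {
    if (is.null(sigma_r)) sigma_r <- stats::rexp(1, 1 / prior$sigma_r_mean)
    if (is.null(sigma_n)) sigma_n <- stats::rexp(1, 1 / prior$sigma_n_mean)
    pi <- stats::rgamma(4, 1); pi <- pi / sum(pi)
    nr_parameters(pi = pi,
                  kappa = exp(stats::rnorm(1, prior$log_kappa_mean,
                                           prior$log_kappa_sd)),
                  eps_r = stats::rnorm(6, 0, sigma_r),
                  eps_n = stats::rnorm(12, 0, sigma_n),
                  sigma_r = sigma_r, sigma_n = sigma_n,
                  alpha = alpha, K = K)
  } else {
    if (is.null(s)) s <- stats::rexp(1, 1 / prior$s_mean)
    rho_raw <- stats::rexp(6, 1 / prior$rho_mean)
    a_root <- stats::rnorm(3, 0, prior$a_root_sd)
    keys <- rt_clade_keys(tr)
    root_kids <- c(tr$kid1[tr$root], tr$kid2[tr$root])
    a_of <- stats::setNames(vector("list", rt_nnode_total(tr)), NULL)
    pi_branch <- list()
    for (v in rt_preorder(tr)) {
      if (v == tr$root) next
      if (v %in% root_kids) { a_of[[v]] <- a_root; next }
      a_par <- a_of[[tr$par[v]]]
      a_of[[v]] <- stats::rnorm(3, a_par, s)
      pi_branch[[keys[v]]] <- composition_vector(alr_inv(a_of[[v]]))
    }
    hb_parameters(tree, rho = rho_raw, pi_root = alr_inv(a_root),
                  pi_branch = pi_branch, s = s, alpha = alpha, K = K)
  }
}
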