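# Metropolis-Hastings MCMC over rooted topology, branch lengths and model
# parameters, for both the NR and HB models.

#' MCMC options
#'
#' @param n_iter Total iterations (one proposed move each).
#' @param burnin Burn-in fraction of `n_iter` discarded before recording
#'   (default 0.25), or an absolute iteration count if `>= 1`.
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param move_weights Named weights for the move groups `brlen`, `nni`,
#'   `reroot` and `params` (defaults 0.4 / 0.1 / 0.1 / 0.4; parameter mass is
#'   split evenly across the model's parameter moves).
#' @param log_every Emit one structured progress line (iteration,
#'   log-likelihood, log-prior, acceptance rate) every this many iterations;
#'   `0` (default) disables logging.
#' @param scales Named list of proposal scales: `brlen_lambda`, `pi_sd`,
#'   `kappa_sd`, `alpha_lambda`, `eps_sd`, `sigma_lambda`, `a_sd`,
#'   `rho_lambda`, `s_lambda`.
#' @return Object of class `mcmc_options`.
#' @export
mcmc_options <- function(n_iter = 10000, burnin = 0.25, thin = 10,
                         move_weights = c(brlen = 0.4, nni = 0.1,
                                          reroot = 0.1, params = 0.4),
                         scales = list(), log_every = 0) {
  stopifnot(n_iter >= 1, thin >= 1, burnin >= 0, log_every >= 0)
  defaults <- list(brlen_lambda = 1, pi_sd = 0.15, kappa_sd = 0.3,
                   alpha_lambda = 0.7, eps_sd = 0.15, sigma_lambda = 1.2,
                   a_sd = 0.3, rho_lambda = 0.6, s_lambda = 1.2)
  unknown <- setdiff(names(scales), names(defaults))
  if (length(unknown)) stop("unknown proposal scales: ",
                            paste(unknown, collapse = ", "))
  defaults[names(scales)] <- scales
  w <- c(brlen = 0.4, nni = 0.1, reroot = 0.1, params = 0.4)
  w[names(move_weights)] <- move_weights
  structure(list(n_iter = as.integer(n_iter), burnin = burnin,
                 thin = as.integer(thin), move_weights = w / sum(w),
                 scales = defaults, log_every = as.integer(log_every)),
            class = "mcmc_options")
}

## --- internal state -------------------------------------------------------
# NR: list(model, tr, pi, log_kappa, eps_r, eps_n, sigma_r, sigma_n, alpha)
# HB: list(model, tr, rho_raw, a_root, a_edge (3 x nnode, cols valid only for
#     non-root, non-root-adjacent nodes), s, alpha)

# Initial state: hyperparameters from the prior; HB compositions seeded at
# the empirical composition of the clade below each edge (plus pseudocounts)
# when data are present, so composition burn-in starts near the data rather
# than at an arbitrary point of the wide prior.
state_from_prior <- function(tr, model, prior, K, aln = NULL) {
  st <- list(model = model, tr = tr, K = K)
  has_data <- !is.null(aln) && aln$n_sites > 0L
  if (model == "NR") {
    st$sigma_r <- stats::rexp(1, 1 / prior$sigma_r_mean)
    st$sigma_n <- stats::rexp(1, 1 / prior$sigma_n_mean)
    p <- stats::rgamma(4, 1); st$pi <- p / sum(p)
    st$log_kappa <- stats::rnorm(1, prior$log_kappa_mean, prior$log_kappa_sd)
    st$eps_r <- stats::setNames(stats::rnorm(6, 0, st$sigma_r), PAIRS6)
    st$eps_n <- stats::setNames(stats::rnorm(12, 0, st$sigma_n), PAIRS12)
    if (has_data) {
      counts <- table(factor(aln$seq[aln$seq %in% NUC], levels = NUC))
      st$pi <- as.numeric(counts + 1) / sum(counts + 1)
    }
  } else {
    st$s <- stats::rexp(1, 1 / prior$s_mean)
    st$rho_raw <- stats::rexp(6, 1 / prior$rho_mean)
    nn <- rt_nnode_total(tr)
    st$a_edge <- matrix(NA_real_, 3, nn)
    rk <- c(tr$kid1[tr$root], tr$kid2[tr$root])
    if (has_data) {
      tu <- rt_tips_under(tr)
      emp_a <- function(tips) {
        seqs <- aln$seq[match(tr$labels[tips], aln$labels), , drop = FALSE]
        counts <- table(factor(seqs[seqs %in% NUC], levels = NUC))
        alr(as.numeric(counts + 1) / sum(counts + 1))
      }
      st$a_root <- emp_a(seq_len(tr$ntip))
      for (v in seq_len(nn)) {
        if (v == tr$root || v %in% rk) next
        st$a_edge[, v] <- emp_a(tu[[v]])
      }
    } else {
      st$a_root <- stats::rnorm(3, 0, prior$a_root_sd)
      for (v in rt_preorder(tr)) {
        if (v == tr$root || v %in% rk) next
        p <- tr$par[v]
        a_par <- if (p %in% rk) st$a_root else st$a_edge[, p]
        st$a_edge[, v] <- stats::rnorm(3, a_par, st$s)
      }
    }
  }
  st$alpha <- stats::rexp(1, 1 / prior$alpha_mean)
  st
}

# alr coordinates of the composition on the edge owned by non-root node v
a_of_edge <- function(st, v) {
  if (st$tr$par[v] == st$tr$root) st$a_root else st$a_edge[, v]
}

state_log_prior <- function(st, prior) {
  tr <- st$tr
  el <- tr$elen[-tr$root]
  if (any(el <= 0)) return(-Inf)
  lp <- sum(stats::dexp(el, rate = 1 / prior$brlen_mean, log = TRUE))
  if (st$model == "NR") {
    if (st$sigma_r <= 0 || st$sigma_n <= 0 || st$alpha <= 0) return(-Inf)
    lp <- lp + lgamma(4) +
      stats::dnorm(st$log_kappa, prior$log_kappa_mean, prior$log_kappa_sd,
                   log = TRUE) +
      sum(stats::dnorm(st$eps_r, 0, st$sigma_r, log = TRUE)) +
      sum(stats::dnorm(st$eps_n, 0, st$sigma_n, log = TRUE)) +
      stats::dexp(st$sigma_r, 1 / prior$sigma_r_mean, log = TRUE) +
      stats::dexp(st$sigma_n, 1 / prior$sigma_n_mean, log = TRUE)
  } else {
    if (st$s <= 0 || st$alpha <= 0 || any(st$rho_raw <= 0)) return(-Inf)
    lp <- lp + sum(stats::dexp(st$rho_raw, 1 / prior$rho_mean, log = TRUE)) +
      dnorm3(st$a_root, 0, prior$a_root_sd) +
      stats::dexp(st$s, 1 / prior$s_mean, log = TRUE)
    rk <- c(tr$kid1[tr$root], tr$kid2[tr$root])
    vs <- setdiff(seq_len(rt_nnode_total(tr)), c(tr$root, rk))
    ps <- tr$par[vs]
    a_par <- st$a_edge[, ps, drop = FALSE]
    a_par[, ps %in% rk] <- st$a_root
    lp <- lp + sum(stats::dnorm(st$a_edge[, vs, drop = FALSE] - a_par,
                                0, st$s, log = TRUE))
  }
  lp + stats::dexp(st$alpha, 1 / prior$alpha_mean, log = TRUE)
}

# Log-likelihood of an internal state; `cache` holds tip partials (tips in
# rtree id order 1..n), pattern weights and K.  Returns -Inf on degenerate
# parameter combinations (auto-reject).
state_loglik <- function(st, cache) {
  if (cache$n_pat == 0L) return(0)
  tr <- st$tr
  eds <- rt_postorder_edges(tr)
  elen <- tr$elen[eds[, "child"]]
  if (st$model == "NR") {
    qq <- nr_Q_fast(st$pi, exp(st$log_kappa), st$eps_r, st$eps_n)
    if (is.null(qq)) return(-Inf)
    Qs <- array(qq$Q, c(4, 4, 1))
    root_dist <- qq$stat
  } else {
    rho <- st$rho_raw / mean(st$rho_raw)
    pi_root <- alr_inv(st$a_root)
    if (any(!is.finite(pi_root)) || any(pi_root <= 0)) return(-Inf)
    ne <- nrow(eds)
    Qs <- array(0, c(4, 4, ne))
    for (e in seq_len(ne)) {
      ch <- eds[e, "child"]
      pi_e <- if (tr$par[ch] == tr$root) pi_root else alr_inv(st$a_edge[, ch])
      if (any(pi_e <= 0) || any(!is.finite(pi_e))) return(-Inf)
      Qs[, , e] <- gtr_Q_fast(rho, pi_e)
    }
    root_dist <- pi_root
  }
  rates <- discrete_gamma_rates(st$alpha, cache$K)
  ll <- prune_loglik_cpp(matrix(as.integer(eds), ncol = 2L), tr$ntip,
                         rt_nnode_total(tr), tr$root, cache$tp,
                         cache$weights, Qs, elen, rates,
                         as.numeric(root_dist))
  if (!is.finite(ll)) return(-Inf)
  ll
}

## --- proposals ------------------------------------------------------------
# Each proposal returns list(state, log_hastings, prior_only)

propose_brlen <- function(st, sc) {
  tr <- st$tr
  v <- sample.int(rt_nnode_total(tr), 1L)
  while (v == tr$root) v <- sample.int(rt_nnode_total(tr), 1L)
  m <- exp(sc$brlen_lambda * (stats::runif(1) - 0.5))
  st$tr$elen[v] <- tr$elen[v] * m
  list(state = st, log_hastings = log(m), prior_only = FALSE)
}

propose_nni <- function(st, sc) {
  tr <- st$tr
  cand <- rt_nni_candidates(tr)
  if (!length(cand)) return(NULL)
  v <- cand[sample.int(length(cand), 1L)]
  res <- rt_nni(tr, v, sample.int(2L, 1L))
  st$tr <- res$tree
  lh <- 0
  if (st$model == "HB" && res$at_root) {
    # x = swapped_up becomes root-adjacent (surrenders its composition);
    # w = swapped_down leaves the root and needs one.  Two variants, chosen
    # with equal probability (each is its own reverse):
    #   swap  — w inherits x's composition (deterministic bijection, HR 0);
    #   fresh — w draws from its conditional prior, with the forward and
    #           reverse densities in the Hastings ratio.
    x <- res$swapped_up; w <- res$swapped_down
    a_old_x <- st$a_edge[, x]
    if (stats::runif(1) < 0.5) {
      st$a_edge[, w] <- a_old_x
      st$a_edge[, x] <- NA_real_
    } else {
      lh <- lh + dnorm3(a_old_x, st$a_root, st$s)    # reverse regeneration
      st$a_edge[, x] <- NA_real_
      a_new_w <- stats::rnorm(3, st$a_root, st$s)
      lh <- lh - dnorm3(a_new_w, st$a_root, st$s)    # forward draw
      st$a_edge[, w] <- a_new_w
    }
  }
  list(state = st, log_hastings = lh, prior_only = FALSE)
}

propose_reroot <- function(st, sc) {
  tr <- st$tr
  owners <- setdiff(seq_len(rt_nnode_total(tr)), c(tr$root, tr$kid2[tr$root]))
  o <- owners[sample.int(length(owners), 1L)]
  frac <- stats::runif(1)
  if (tr$par[o] == tr$root) {
    st$tr <- rt_reroot(tr, o, frac)$tree
    return(list(state = st, log_hastings = 0, prior_only = FALSE))
  }
  hb <- st$model == "HB"
  lh <- 0
  # HB: the edge rooted on splits into the two new root edges (its
  # composition is surrendered), and the merged old-root edge needs one.
  # Two variants with equal probability, each its own reverse:
  #   swap  — the rooted-on edge's composition becomes the new root
  #           composition and the merged edge inherits the old root
  #           composition (deterministic bijection, Jacobian 1);
  #   fresh — the merged edge draws from its conditional prior; the rooted-on
  #           edge's old composition enters the reverse density.
  swap <- hb && stats::runif(1) < 0.5
  if (hb && !swap)
    lh <- lh + dnorm3(st$a_edge[, o], a_of_edge(st, tr$par[o]), st$s)
  a_old_o <- if (hb) st$a_edge[, o] else NULL
  a_old_root <- if (hb) st$a_root else NULL
  L_e <- tr$elen[o]
  res <- rt_reroot(tr, o, frac)
  st$tr <- res$tree
  L_f <- res$tree$elen[res$merged]
  lh <- lh + log(L_e) - log(L_f)
  if (hb) {
    aE <- st$a_edge
    if (!is.null(res$flipped))   # composition travels with the unrooted edge
      aE[, unname(res$flipped)] <- st$a_edge[, as.integer(names(res$flipped))]
    aE[, res$new_root_children] <- NA_real_
    st$a_edge <- aE
    if (swap) {
      st$a_root <- a_old_o
      st$a_edge[, res$merged] <- a_old_root
    } else {
      a_par <- a_of_edge(st, st$tr$par[res$merged])
      a_new <- stats::rnorm(3, a_par, st$s)
      lh <- lh - dnorm3(a_new, a_par, st$s)
      st$a_edge[, res$merged] <- a_new
    }
  }
  list(state = st, log_hastings = lh, prior_only = FALSE)
}

propose_param <- function(st, sc, prior) {
  if (st$model == "NR") {
    moves <- c("pi", "kappa", "alpha", "eps_r", "eps_n", "sigma_r", "sigma_n",
               "rescale_r", "rescale_n", "kappa_ridge", "eps_ridge")
  } else {
    moves <- c("rho", "a_root", "a_edge", "s", "alpha", "rescale_s")
  }
  mv <- moves[sample.int(length(moves), 1L)]
  lh <- 0; prior_only <- FALSE
  # mixture of step sizes for the random walks: occasional large jumps help
  # traversal, small steps refine
  stepf <- c(0.3, 1, 3)[sample.int(3L, 1L)]
  switch(mv,
    pi = {
      a <- alr(st$pi) + stats::rnorm(3, 0, stepf * sc$pi_sd)
      pi_new <- alr_inv(a)
      lh <- sum(log(pi_new)) - sum(log(st$pi))  # alr Jacobian ratio
      st$pi <- pi_new
    },
    kappa = st$log_kappa <- st$log_kappa + stats::rnorm(1, 0, sc$kappa_sd),
    # kappa and the two transition entries of eps_r only enter the rate
    # matrix through their product, so shifting log kappa by d and those
    # eps_r entries by -d leaves the likelihood exactly invariant.  The
    # conditional of the shift under the prior is Gaussian, so draw it as a
    # Gibbs step (the compensating Hastings term makes the acceptance 1).
    kappa_ridge = {
      A <- 1 / prior$log_kappa_sd^2 + 2 / st$sigma_r^2
      b <- (prior$log_kappa_mean - st$log_kappa) / prior$log_kappa_sd^2 +
        (st$eps_r["AG"] + st$eps_r["CT"]) / st$sigma_r^2
      m <- as.numeric(b / A)
      if (!is.finite(A) || !is.finite(m)) { A <- 1; m <- 0; d <- 0 }
      else d <- stats::rnorm(1, m, sqrt(1 / A))
      st$log_kappa <- st$log_kappa + d
      st$eps_r["AG"] <- st$eps_r["AG"] - d
      st$eps_r["CT"] <- st$eps_r["CT"] - d
      lh <- ((d - m)^2 - m^2) * A / 2
      prior_only <- TRUE
    },
    # same exact redundancy between an unordered eps_r entry and the two
    # ordered eps_n entries of that pair
    eps_ridge = {
      i <- sample.int(6L, 1L)
      pair <- PAIRS6[i]
      rev_pair <- paste0(substr(pair, 2, 2), substr(pair, 1, 1))
      A <- 1 / st$sigma_r^2 + 2 / st$sigma_n^2
      b <- -st$eps_r[pair] / st$sigma_r^2 +
        (st$eps_n[pair] + st$eps_n[rev_pair]) / st$sigma_n^2
      m <- as.numeric(b / A)
      if (!is.finite(A) || !is.finite(m)) { A <- 1; m <- 0; d <- 0 }
      else d <- stats::rnorm(1, m, sqrt(1 / A))
      st$eps_r[pair] <- st$eps_r[pair] + d
      st$eps_n[pair] <- st$eps_n[pair] - d
      st$eps_n[rev_pair] <- st$eps_n[rev_pair] - d
      lh <- ((d - m)^2 - m^2) * A / 2
      prior_only <- TRUE
    },
    alpha = {
      m <- exp(sc$alpha_lambda * (stats::runif(1) - 0.5))
      st$alpha <- st$alpha * m; lh <- log(m)
      prior_only <- st$K == 1L
    },
    eps_r = {
      i <- sample.int(6L, 1L)
      st$eps_r[i] <- st$eps_r[i] + stats::rnorm(1, 0, stepf * sc$eps_sd)
    },
    eps_n = {
      i <- sample.int(12L, 1L)
      st$eps_n[i] <- st$eps_n[i] + stats::rnorm(1, 0, stepf * sc$eps_sd)
    },
    sigma_r = {
      m <- exp(sc$sigma_lambda * (stats::runif(1) - 0.5))
      st$sigma_r <- st$sigma_r * m; lh <- log(m); prior_only <- TRUE
    },
    sigma_n = {
      m <- exp(sc$sigma_lambda * (stats::runif(1) - 0.5))
      st$sigma_n <- st$sigma_n * m; lh <- log(m); prior_only <- TRUE
    },
    # joint rescale moves traverse the (sigma, eps) funnel: scale the
    # hyperparameter and its whole perturbation vector together; the
    # deterministic map has Jacobian m^(d+1)
    rescale_r = {
      m <- exp(sc$sigma_lambda * (stats::runif(1) - 0.5))
      st$sigma_r <- st$sigma_r * m
      st$eps_r <- st$eps_r * m
      lh <- 7 * log(m)
    },
    rescale_n = {
      m <- exp(sc$sigma_lambda * (stats::runif(1) - 0.5))
      st$sigma_n <- st$sigma_n * m
      st$eps_n <- st$eps_n * m
      lh <- 13 * log(m)
    },
    rescale_s = {
      m <- exp(sc$sigma_lambda * (stats::runif(1) - 0.5))
      tr <- st$tr
      rk <- c(tr$kid1[tr$root], tr$kid2[tr$root])
      a_old <- st$a_edge  # increments are relative to the *old* positions
      n_edges <- 0L
      for (v in rt_preorder(tr)) {
        if (v == tr$root || v %in% rk) next
        p <- tr$par[v]
        old_par <- if (p %in% rk) st$a_root else a_old[, p]
        new_par <- if (p %in% rk) st$a_root else st$a_edge[, p]
        st$a_edge[, v] <- new_par + m * (a_old[, v] - old_par)
        n_edges <- n_edges + 1L
      }
      st$s <- st$s * m
      lh <- (3 * n_edges + 1) * log(m)
    },
    rho = {
      i <- sample.int(6L, 1L)
      m <- exp(sc$rho_lambda * (stats::runif(1) - 0.5))
      st$rho_raw[i] <- st$rho_raw[i] * m; lh <- log(m)
    },
    a_root = st$a_root <- st$a_root + stats::rnorm(3, 0, stepf * sc$a_sd),
    a_edge = {
      tr <- st$tr
      rk <- c(tr$kid1[tr$root], tr$kid2[tr$root])
      elig <- setdiff(seq_len(rt_nnode_total(tr)), c(tr$root, rk))
      v <- elig[sample.int(length(elig), 1L)]
      st$a_edge[, v] <- st$a_edge[, v] + stats::rnorm(3, 0, stepf * sc$a_sd)
    },
    s = {
      m <- exp(sc$s_lambda * (stats::runif(1) - 0.5))
      st$s <- st$s * m; lh <- log(m); prior_only <- TRUE
    })
  list(state = st, log_hastings = lh, prior_only = prior_only,
       sub_move = mv)
}

## --- driver ---------------------------------------------------------------

#' Run the Metropolis-Hastings sampler
#'
#' Samples the posterior over rooted topology, branch lengths and model
#' parameters under the NR or HB model, using a random-scan move set:
#' branch-length multipliers, rooted nearest-neighbour interchanges,
#' re-rooting on a uniformly chosen edge, and random-walk parameter moves on
#' unconstrained scales (log for positive scalars, alr for compositions).
#' HB composition vectors travel with their edges under topology moves;
#' edges that become root-adjacent surrender theirs, and edges that leave the
#' root draw a fresh vector from its conditional prior, with the proposal
#' densities folded into the Hastings ratio so the chain stays in detailed
#' balance.
#'
#' @param aln An [nt_alignment()]; a zero-site alignment gives a
#'   constant-likelihood run that samples the prior (useful for validation).
#' @param model `"NR"` or `"HB"`.
#' @param tree Starting rooted binary `phylo`, or `NULL` for a random
#'   starting tree.
#' @param options [mcmc_options()].
#' @param prior [prior_spec()].
#' @param K Number of discrete-gamma rate categories (fixed for the run;
#'   `K = 1` disables rate heterogeneity).
#' @param seed Integer seed; the run is reproducible given `(seed, options)`.
#' @return Object of class `root_mcmc`: list with `trace` (tibble of scalar
#'   samples: iteration, log-likelihood, log-prior, model scalars, root
#'   split), `samples` (list of retained states: tree plus parameters),
#'   `acceptance` (tibble of per-move acceptance rates), and the run
#'   metadata.  Use [tidy.root_mcmc()], [glance.root_mcmc()],
#'   [root_split_posterior()], [majority_rule_consensus()] and friends on it.
#' @export
run_mcmc <- function(aln, model = c("NR", "HB"), tree = NULL,
                     options = mcmc_options(), prior = prior_spec(),
                     K = 4, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "nt_alignment"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) {
    tr <- rt_random(sort(aln$labels),
                    rlen = function(k) stats::rexp(k, 1 / prior$brlen_mean))
  } else {
    tr <- rt_from_phylo(validate_rooted_tree(tree))
    if (!setequal(tr$labels, aln$labels))
      stop("tree leaves and alignment taxa differ")
  }
  cp <- compress_patterns(aln)
  cache <- list(tp = tip_partials(cp$patterns, aln$labels, tr$labels),
                weights = as.numeric(cp$weights), K = as.integer(K),
                n_pat = length(cp$weights))
  st <- state_from_prior(tr, model, prior, as.integer(K), aln)
  lp <- state_log_prior(st, prior)
  ll <- state_loglik(st, cache)
  if (!is.finite(lp) || !is.finite(ll))
    stop("initial state has non-finite posterior density")
  opt <- options
  burn <- if (opt$burnin < 1) floor(opt$burnin * opt$n_iter)
          else as.integer(opt$burnin)
  groups <- names(opt$move_weights)
  n_prop <- stats::setNames(numeric(4), groups)
  n_acc <- stats::setNames(numeric(4), groups)
  keep <- which(seq_len(opt$n_iter) > burn &
                ((seq_len(opt$n_iter) - burn) %% opt$thin == 0L))
  samples <- vector("list", length(keep))
  ki <- 0L
  for (it in seq_len(opt$n_iter)) {
    g <- groups[sample.int(4L, 1L, prob = opt$move_weights)]
    prop <- switch(g,
                   brlen = propose_brlen(st, opt$scales),
                   nni = propose_nni(st, opt$scales),
                   reroot = propose_reroot(st, opt$scales),
                   params = propose_param(st, opt$scales, prior))
    n_prop[g] <- n_prop[g] + 1
    if (!is.null(prop)) {
      lp2 <- state_log_prior(prop$state, prior)
      if (is.finite(lp2)) {
        ll2 <- if (prop$prior_only) ll else state_loglik(prop$state, cache)
        log_acc <- (ll2 + lp2) - (ll + lp) + prop$log_hastings
        if (is.finite(ll2) && log(stats::runif(1)) < log_acc) {
          st <- prop$state; ll <- ll2; lp <- lp2
          n_acc[g] <- n_acc[g] + 1
        }
      }
    }
    if (ki < length(keep) && it == keep[ki + 1L]) {
      ki <- ki + 1L
      samples[[ki]] <- record_sample(st, it, ll, lp)
    }
    if (isTRUE(opt$log_every > 0L) && it %% opt$log_every == 0L)
      message(sprintf("iter %d  logL %.3f  logPrior %.3f  accept %.3f",
                      it, ll, lp, sum(n_acc) / max(1, sum(n_prop))))
  }
  trace <- do.call(rbind, lapply(samples, trace_row))
  structure(list(model = model, samples = samples,
                 trace = tibble::as_tibble(trace),
                 acceptance = tibble::tibble(
                   move = groups, proposed = as.integer(n_prop),
                   accepted = as.integer(n_acc),
                   rate = ifelse(n_prop > 0, n_acc / n_prop, NA_real_)),
                 options = opt, prior = prior, K = as.integer(K),
                 seed = seed, labels = tr$labels, n_sites = aln$n_sites),
            class = "root_mcmc")
}

# One retained draw: tree + parameters + densities + derived per-clade info.
record_sample <- function(st, it, ll, lp) {
  tr <- st$tr
  out <- list(iteration = it, ll = ll, lp = lp,
              tree = tr, root_split = rt_root_split_key(tr))
  if (st$model == "NR") {
    out$params <- list(pi = st$pi, kappa = exp(st$log_kappa),
                       eps_r = st$eps_r, eps_n = st$eps_n,
                       sigma_r = st$sigma_r, sigma_n = st$sigma_n,
                       alpha = st$alpha)
  } else {
    pi_root <- alr_inv(st$a_root)
    out$params <- list(rho = st$rho_raw / mean(st$rho_raw),
                       pi_root = pi_root, s = st$s, alpha = st$alpha,
                       a_edge = st$a_edge)
  }
  out$model <- st$model
  out
}

trace_row <- function(smp) {
  base <- data.frame(iteration = smp$iteration,
                     log_likelihood = smp$ll, log_prior = smp$lp,
                     root_split = smp$root_split,
                     stringsAsFactors = FALSE)
  if (smp$model == "NR") {
    cbind(base, data.frame(kappa = smp$params$kappa,
                           alpha = smp$params$alpha,
                           sigma_r = smp$params$sigma_r,
                           sigma_n = smp$params$sigma_n,
                           pi_A = smp$params$pi[1], pi_C = smp$params$pi[2],
                           pi_G = smp$params$pi[3], pi_T = smp$params$pi[4]))
  } else {
    cbind(base, data.frame(s = smp$params$s, alpha = smp$params$alpha,
                           root_gc = unname(smp$params$pi_root[2] +
                                            smp$params$pi_root[3])))
  }
}

#' @export
print.root_mcmc <- function(x, ...) {
  cat("Rooted-tree MCMC fit (", x$model, " model)\n", sep = "")
  cat("  taxa: ", length(x$labels), ", sites: ", x$n_sites,
      ", retained samples: ", length(x$samples), "\n", sep = "")
  top <- root_split_posterior(x)
  cat("  modal root split: ", top$split[1],
      sprintf(" (PP = %.3f)", top$probability[1]), "\n", sep = "")
  invisible(x)
}
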