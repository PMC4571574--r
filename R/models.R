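# Rate-matrix construction for HKY85 / GTR / NR / HB, stationary
# distributions, transition probabilities and discrete-gamma rates.
# Nucleotide order is A, C, G, T everywhere.

NUC <- c("A", "C", "G", "T")
PAIRS6 <- c("AC", "AG", "AT", "CG", "CT", "GT")          # unordered pairs
PAIRS12 <- c("AC", "AG", "AT", "CA", "CG", "CT",
             "GA", "GC", "GT", "TA", "TC", "TG")          # ordered pairs
TRANSITIONS <- c("AG", "GA", "CT", "TC")

#' Composition vector
#'
#' Nucleotide frequencies in A, C, G, T order — the theoretical stationary
#' distribution of a reversible process, or the per-branch composition of the
#' HB model.
#'
#' @param p Numeric length-4 vector of probabilities (A, C, G, T).
#' @return Named, validated numeric vector.
#' @export
composition_vector <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 4L || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("composition must be 4 probabilities strictly inside (0,1)")
  if (abs(sum(p) - 1) > 1e-12) stop("composition must sum to 1 (within 1e-12)")
  stats::setNames(p, NUC)
}

#' GC content of a composition vector
#'
#' `pi_G + pi_C`; the statistic by which branches are ranked in HB posterior
#' summaries.
#'
#' @param pi Composition vector (A, C, G, T).
#' @return Numeric scalar in (0, 1).
#' @export
gc_content <- function(pi) {
  pi <- composition_vector(pi)
  unname(pi["G"] + pi["C"])
}

check_rate_matrix_inputs <- function(pi, kappa = 1) {
  pi <- composition_vector(pi)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be a positive real")
  pi
}

finish_rate_matrix <- function(Q, normalize = TRUE, stat = NULL) {
  dimnames(Q) <- list(NUC, NUC)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    if (is.null(stat)) stat <- stationary_distribution(Q)
    rate <- -sum(stat * diag(Q))
    if (rate <= 0) stop("degenerate rate matrix: zero mean rate")
    Q <- Q / rate
  }
  attr(Q, "normalized") <- normalize
  Q
}

#' HKY85 rate matrix
#'
#' `q_ij = pi_j * kappa` for transitions (A<->G, C<->T), `q_ij = pi_j` for
#' transversions; normalized so the expected substitution rate at
#' stationarity is 1 (branch lengths in expected substitutions per site).
#'
#' @param pi Composition vector (A, C, G, T).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return 4x4 rate matrix with stationary distribution `pi`.
#' @examples
#' hky_rate_matrix(rep(0.25, 4), 1)  # Jukes-Cantor
#' @export
hky_rate_matrix <- function(pi, kappa) {
  pi <- check_rate_matrix_inputs(pi, kappa)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    pair <- paste0(NUC[i], NUC[j])
    Q[i, j] <- pi[j] * if (pair %in% TRANSITIONS) kappa else 1
  }
  finish_rate_matrix(Q, stat = pi)
}

#' GTR rate matrix
#'
#' `q_ij = rho_ij * pi_j` with symmetric exchangeabilities `rho` — the
#' within-branch process of the HB model.  Reversible with stationary
#' distribution `pi`.
#'
#' @param rho Exchangeabilities, length 6, order (AC, AG, AT, CG, CT, GT);
#'   normalized internally to mean 1.
#' @param pi Composition vector (A, C, G, T).
#' @param normalize Scale to mean rate 1 under `pi` (default `TRUE`).
#' @return 4x4 rate matrix.
#' @export
gtr_rate_matrix <- function(rho, pi, normalize = TRUE) {
  pi <- composition_vector(pi)
  rho <- as.numeric(rho)
  if (length(rho) != 6L || any(!is.finite(rho)) || any(rho <= 0))
    stop("rho must be 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)")
  rho <- rho / mean(rho)
  names(rho) <- PAIRS6
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    pair <- paste0(sort(c(NUC[i], NUC[j])), collapse = "")
    Q[i, j] <- rho[pair] * pi[j]
  }
  finish_rate_matrix(Q, normalize = normalize, stat = pi)
}

#' Non-reversible (NR) rate matrix
#'
#' The NR model's rate matrix: an HKY85 core with two multiplicative
#' log-scale perturbations,
#' `q_ij = pi_j * kappa_ij * exp(eps_r[{i,j}]) * exp(eps_n[(i,j)])`,
#' where `eps_r` (6 values, one per unordered pair) opens the model up to GTR
#' structure and `eps_n` (12 values, one per ordered pair) to the fully
#' general non-reversible form.  Normalized to mean rate 1 under its *own*
#' stationary distribution, so branch lengths remain expected
#' substitutions/site under the actual process.
#'
#' @param pi Base composition (A, C, G, T) of the HKY85 core.
#' @param kappa Transition/transversion ratio of the core.
#' @param eps_r Length-6 reversible perturbations (order `AC,AG,AT,CG,CT,GT`).
#' @param eps_n Length-12 non-reversible perturbations (ordered pairs
#'   `AC,AG,AT,CA,CG,CT,GA,GC,GT,TA,TC,TG`).
#' @return 4x4 normalized rate matrix; generally non-reversible when
#'   `eps_n != 0`.
#' @export
nr_rate_matrix <- function(pi, kappa, eps_r = rep(0, 6), eps_n = rep(0, 12)) {
  pi <- check_rate_matrix_inputs(pi, kappa)
  eps_r <- as.numeric(eps_r); eps_n <- as.numeric(eps_n)
  if (length(eps_r) != 6L || any(!is.finite(eps_r)))
    stop("eps_r must be 6 finite reals")
  if (length(eps_n) != 12L || any(!is.finite(eps_n)))
    stop("eps_n must be 12 finite reals")
  names(eps_r) <- PAIRS6; names(eps_n) <- PAIRS12
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ord <- paste0(NUC[i], NUC[j])
    unord <- paste0(sort(c(NUC[i], NUC[j])), collapse = "")
    kap <- if (ord %in% TRANSITIONS) kappa else 1
    Q[i, j] <- pi[j] * kap * exp(eps_r[unord]) * exp(eps_n[ord])
  }
  finish_rate_matrix(Q)
}

#' Stationary distribution of a rate matrix
#'
#' The unique probability vector `v` with `v Q = 0` for an irreducible `Q`.
#' For the NR model this is also the root distribution, since NR is
#' stationary.
#'
#' @param Q 4x4 rate matrix (rows sum to zero, off-diagonals positive).
#' @return Composition vector.
#' @export
stationary_distribution <- function(Q) {
  if (!is.matrix(Q) || any(dim(Q) != 4L)) stop("Q must be a 4x4 matrix")
  A <- rbind(t(Q), rep(1, 4))
  v <- tryCatch(qr.solve(A, c(0, 0, 0, 0, 1)),
                error = function(e) stop("degenerate rate matrix: ",
                                         conditionMessage(e), call. = FALSE))
  if (any(v <= 0)) stop("rate matrix is reducible or degenerate")
  resid <- max(abs(v %*% Q))
  if (resid > 1e-10) stop("stationary solve residual too large: ", resid)
  stats::setNames(as.numeric(v / sum(v)), NUC)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)`.  Uses the eigendecomposition of `Q` (complex-safe, since
#' non-reversible matrices can have complex eigenvalues) with a
#' scaling-and-squaring fallback ([Matrix::expm()]) when the eigenvector
#' matrix is ill-conditioned.
#'
#' @param Q 4x4 rate matrix.
#' @param t Elapsed time (branch length x rate), `t >= 0`.
#' @return 4x4 row-stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be a non-negative real")
  if (t == 0) return(diag(4))
  P <- NULL
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (!is.null(e)) {
    Vi <- tryCatch(solve(e$vectors), error = function(err) NULL)
    if (!is.null(Vi)) {
      P <- Re(e$vectors %*% (exp(e$values * t) * Vi))
      if (any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-8) P <- NULL
    }
  }
  if (is.null(P))
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(NUC, NUC)
  P
}

#' Discrete-gamma rate categories
#'
#' `K` equal-probability categories of a Gamma(shape `alpha`, mean 1)
#' distribution; each category rate is the conditional mean of its quantile
#' band (not the median), renormalized so the category rates average exactly
#' 1.
#'
#' @param alpha Gamma shape (> 0); small values mean strong rate
#'   heterogeneity across sites.
#' @param K Number of categories (>= 1); `K = 1` disables rate heterogeneity.
#' @return Numeric vector of `K` rates with mean 1, each with prior weight
#'   `1/K`.
#' @examples
#' discrete_gamma_rates(1, 2)  # c(0.30685, 1.69315)
#' @export
discrete_gamma_rates <- function(alpha, K) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  if (K == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
  # E[X ; a < X < b] for Gamma(alpha, alpha) = F_{alpha+1}(b) - F_{alpha+1}(a)
  bands <- diff(stats::pgamma(q, shape = alpha + 1, rate = alpha))
  rates <- bands * K
  rates / mean(rates)
}

## --- parameter blocks -----------------------------------------------------

#' NR model parameters
#'
#' Full parameter block of the stationary non-reversible model: HKY85 core
#' (`pi`, `kappa`), reversible perturbations `eps_r` with scale `sigma_r`,
#' non-reversible perturbations `eps_n` with scale `sigma_n`, and
#' discrete-gamma rate heterogeneity (`alpha`, `K`).
#'
#' @param pi Core composition (A, C, G, T).
#' @param kappa Transition/transversion ratio (> 0).
#' @param eps_r,eps_n Perturbations (lengths 6 and 12).
#' @param sigma_r,sigma_n Perturbation standard deviations (>= 0); large
#'   `sigma_n` is evidence of non-reversibility, which is what roots the tree.
#' @param alpha Gamma shape for among-site rate variation.
#' @param K Number of gamma categories (1 disables).
#' @return Object of class `nr_parameters`.
#' @export
nr_parameters <- function(pi = rep(0.25, 4), kappa = 1,
                          eps_r = rep(0, 6), eps_n = rep(0, 12),
                          sigma_r = 0, sigma_n = 0, alpha = 1, K = 1) {
  pi <- check_rate_matrix_inputs(pi, kappa)
  if (sigma_r < 0 || sigma_n < 0) stop("sigma_r and sigma_n must be >= 0")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  obj <- structure(list(pi = pi, kappa = kappa,
                        eps_r = stats::setNames(as.numeric(eps_r), PAIRS6),
                        eps_n = stats::setNames(as.numeric(eps_n), PAIRS12),
                        sigma_r = sigma_r, sigma_n = sigma_n,
                        alpha = alpha, K = as.integer(K)),
                   class = "nr_parameters")
  nr_rate_matrix(pi, kappa, obj$eps_r, obj$eps_n)  # validates
  obj
}

#' HB model parameters
#'
#' Full parameter block of the non-stationary branch-heterogeneous model:
#' GTR exchangeabilities `rho` shared by all branches, a root composition
#' `pi_root` that also applies on the two root-adjacent branches, and one
#' composition per remaining branch (`2n-4` of them for `n` taxa), keyed by
#' the clade (sorted, comma-joined tip labels) below the branch.
#'
#' @param tree Rooted binary `phylo` the parameters refer to.
#' @param rho Exchangeabilities (6, order AC, AG, AT, CG, CT, GT).
#' @param pi_root Root composition.
#' @param pi_branch Named list of composition vectors, one per
#'   non-root-adjacent branch, names = clade keys (see [tree_clades()]).
#' @param s Composition-drift standard deviation (> 0) of the hierarchical
#'   prior tying neighbouring branches together.
#' @param alpha,K Gamma rate heterogeneity as in [nr_parameters()].
#' @return Object of class `hb_parameters`.
#' @export
hb_parameters <- function(tree, rho = rep(1, 6), pi_root = rep(0.25, 4),
                          pi_branch = NULL, s = 0.5, alpha = 1, K = 1) {
  tr <- rt_from_phylo(tree, allow_zero = TRUE)
  keys <- hb_branch_keys(tr)
  if (is.null(pi_branch))
    pi_branch <- stats::setNames(rep(list(composition_vector(pi_root)),
                                     length(keys)), keys)
  if (!setequal(names(pi_branch), keys))
    stop("pi_branch must have exactly one composition per non-root-adjacent ",
         "branch; expected clades: ", paste(keys, collapse = "; "))
  if (!is.finite(s) || s <= 0) stop("s must be positive")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  rho <- as.numeric(rho)
  if (length(rho) != 6L || any(rho <= 0)) stop("rho must be 6 positive values")
  structure(list(rho = stats::setNames(rho / mean(rho), PAIRS6),
                 pi_root = composition_vector(pi_root),
                 pi_branch = lapply(pi_branch, composition_vector)[keys],
                 s = s, alpha = alpha, K = as.integer(K)),
            class = "hb_parameters")
}

# Clade keys of the non-root-adjacent branches of an rtree (2n-4 of them).
hb_branch_keys <- function(tr) {
  keys <- rt_clade_keys(tr)
  excl <- c(tr$root, tr$kid1[tr$root], tr$kid2[tr$root])
  keys[setdiff(seq_len(rt_nnode_total(tr)), excl)]
}

#' Per-branch rate matrices of the HB model
#'
#' Root-adjacent edges evolve under `gtr_rate_matrix(rho, pi_root)`; every
#' other edge `b` under `gtr_rate_matrix(rho, pi_b)`.  Each matrix is
#' normalized to mean rate 1 under its own composition.
#'
#' @param params [hb_parameters()] object.
#' @param tree The rooted binary `phylo` the parameters were built for.
#' @return Named list: `Q` (list of 4x4 matrices, one per edge of
#'   `tree$edge`, in edge order), `root_dist` (the root composition), and
#'   `pi_edge` (list of the composition used on each edge).
#' @export
hb_branch_matrices <- function(params, tree) {
  stopifnot(inherits(params, "hb_parameters"))
  tr <- rt_from_phylo(tree, allow_zero = TRUE)
  keys <- rt_clade_keys(tr)
  if (!setequal(names(params$pi_branch), hb_branch_keys(tr)))
    stop("composition/edge mismatch: parameters were built for a different tree")
  phy <- tree
  root_node <- tr$root
  # map rtree ids to phylo ids: rt_from_phylo preserves phylo numbering
  Qs <- vector("list", nrow(phy$edge))
  pis <- vector("list", nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2L]
    pi_e <- if (phy$edge[i, 1L] == root_node) params$pi_root
            else params$pi_branch[[keys[child]]]
    pis[[i]] <- pi_e
    Qs[[i]] <- gtr_rate_matrix(params$rho, pi_e)
  }
  list(Q = Qs, root_dist = params$pi_root, pi_edge = pis)
}

## --- fast internal constructors (no validation; used by the sampler) ------

# 4x4 matrices of pair indices, built once at load time
local_pair_mats <- function() {
  u <- matrix(0L, 4, 4); o <- matrix(0L, 4, 4); trs <- matrix(FALSE, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    u[i, j] <- match(paste0(sort(c(NUC[i], NUC[j])), collapse = ""), PAIRS6)
    o[i, j] <- match(paste0(NUC[i], NUC[j]), PAIRS12)
    trs[i, j] <- paste0(NUC[i], NUC[j]) %in% TRANSITIONS
  }
  list(unordered = u, ordered = o, transitions = trs)
}
PAIR_MATS <- local_pair_mats()

# GTR Q normalized to mean rate 1 under pi; rho need not be normalized
gtr_Q_fast <- function(rho, pi) {
  R <- matrix(0, 4, 4)
  R[PAIR_MATS$unordered > 0] <- rho[PAIR_MATS$unordered[PAIR_MATS$unordered > 0]]
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# NR Q normalized under its own stationary distribution; returns list(Q, stat)
# or NULL when degenerate
nr_Q_fast <- function(pi, kappa, eps_r, eps_n) {
  M <- matrix(1, 4, 4)
  M[PAIR_MATS$transitions] <- kappa
  E <- matrix(0, 4, 4)
  sel <- PAIR_MATS$unordered > 0
  E[sel] <- eps_r[PAIR_MATS$unordered[sel]] + eps_n[PAIR_MATS$ordered[sel]]
  Q <- M * exp(E) * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 4))
  v <- tryCatch(qr.solve(A, c(0, 0, 0, 0, 1)), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v)) || any(v <= 0)) return(NULL)
  v <- v / sum(v)
  rate <- -sum(v * diag(Q))
  if (!is.finite(rate) || rate <= 0) return(NULL)
  list(Q = Q / rate, stat = v)
}
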