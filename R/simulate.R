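# Generate alignments from the NR or HB model on a known rooted tree — the
# ground-truth generator behind all recovery and calibration tests.

#' Simulate an alignment under the NR or HB model
#'
#' Runs the model generatively, site by site: draw a rate category, draw the
#' root state from the root distribution (NR: the stationary distribution of
#' its rate matrix; HB: `pi_root`), then propagate states from the root to
#' the tips through each branch's transition matrix
#' `P = exp(Q_edge * t * r_k)`.  No indels are introduced: the models
#' describe substitution on pre-aligned sites.  Bit-reproducible for a given
#' seed.
#'
#' @param tree Rooted binary `phylo`.
#' @param params [nr_parameters()] or [hb_parameters()] (also fixes `alpha`
#'   and `K` for the rate categories).
#' @param n_sites Number of sites (>= 1).
#' @param seed Optional integer seed.
#' @return An [nt_alignment()] with attribute `"truth"`: a list with the
#'   generating tree (newick), parameters, seed and per-site rate category
#'   assignments.
#' @examples
#' tr <- read_rooted_tree("((A:0.1,B:0.1):0.1,C:0.2);")
#' aln <- simulate_alignment(tr, nr_parameters(kappa = 2), 100, seed = 1)
#' @export
simulate_alignment <- function(tree, params, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  phy <- tree
  tr <- rt_from_phylo(phy, allow_zero = TRUE)  # zero lengths legal here
  mod <- edge_model_for_phylo(params, phy)
  rates <- discrete_gamma_rates(params$alpha, params$K)
  K <- length(rates)
  cat_of_site <- sample.int(K, n_sites, replace = TRUE)
  root_dist <- as.numeric(mod$root_dist)
  states <- matrix(0L, rt_nnode_total(tr), n_sites)
  states[tr$root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                  prob = root_dist)
  ord <- rt_preorder(tr)
  edge_of_child <- match(seq_len(rt_nnode_total(tr)), phy$edge[, 2L])
  for (v in ord) {
    if (v == tr$root) next
    e <- edge_of_child[v]
    Q <- if (mod$shared) mod$Q[[1L]] else mod$Q[[e]]
    for (k in seq_len(K)) {
      sites_k <- which(cat_of_site == k)
      if (!length(sites_k)) next
      P <- transition_probabilities(Q, phy$edge.length[e] * rates[k])
      par_states <- states[tr$par[v], sites_k]
      for (a in 1:4) {
        idx <- sites_k[par_states == a]
        if (length(idx))
          states[v, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                       prob = P[a, ])
      }
    }
  }
  seqs <- apply(states[seq_len(tr$ntip), , drop = FALSE], 1L,
                function(row) paste(NUC[row], collapse = ""))
  aln <- nt_alignment(stats::setNames(seqs, tr$labels))
  attr(aln, "truth") <- list(tree = write_rooted_tree(phy), params = params,
                             seed = seed, rate_category = cat_of_site)
  aln
}
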