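# Rooted-tree log-likelihood under NR and HB: pruning (fast path) and an
# exhaustive-enumeration oracle used by the test suite.

#' Rooted-tree log-likelihood
#'
#' Felsenstein pruning on the rooted tree, run root-to-tips with the model's
#' transition probabilities: a single normalized non-reversible matrix under
#' NR (root distribution = its stationary distribution) or per-branch GTR
#' matrices under HB (root distribution = `pi_root`).  Sites are independent;
#' discrete-gamma categories are mixed with equal weight `1/K`; gaps and
#' IUPAC ambiguity codes are marginalized over their compatible states.
#' Per-node, per-pattern rescaling keeps the value finite on deep trees.
#'
#' Under a stationary reversible model this value would not depend on where
#' the root is placed (the pulley principle); under NR with `eps_n != 0`, or
#' HB with unequal compositions, it does — this is the likelihood signal that
#' roots the tree.
#'
#' @param aln An [nt_alignment()] whose taxa match the tree's tip labels.
#' @param tree Rooted binary `phylo`.
#' @param params An [nr_parameters()] or [hb_parameters()] object.
#' @return Log-likelihood (finite scalar; `0` for a zero-site alignment).
#' @export
tree_log_likelihood <- function(aln, tree, params) {
  stopifnot(inherits(aln, "nt_alignment"))
  phy <- tree
  if (!setequal(aln$labels, phy$tip.label))
    stop("alignment taxa and tree leaves differ: ",
         paste(symdiff_labels(aln$labels, phy$tip.label), collapse = ", "))
  if (aln$n_sites == 0L) return(0)
  cp <- compress_patterns(aln)
  tp <- tip_partials(cp$patterns, aln$labels, phy$tip.label)
  mod <- edge_model_for_phylo(params, phy)
  tr <- rt_from_phylo(phy)
  eds <- rt_postorder_edges(tr)
  # rt_from_phylo preserves phylo node numbering, so edge rows map directly
  edge_of_child <- match(eds[, "child"], phy$edge[, 2L])
  Qs <- if (mod$shared) array(mod$Q[[1L]], c(4, 4, 1))
        else array(unlist(mod$Q[edge_of_child]), c(4, 4, nrow(eds)))
  elen <- phy$edge.length[edge_of_child]
  rates <- discrete_gamma_rates(params$alpha, params$K)
  ll <- prune_loglik_cpp(matrix(as.integer(eds), ncol = 2L), tr$ntip,
                         rt_nnode_total(tr), tr$root, tp,
                         as.numeric(cp$weights), Qs, elen, rates,
                         as.numeric(mod$root_dist))
  if (!is.finite(ll))
    stop("non-finite log-likelihood (impossible site pattern?)")
  ll
}

symdiff_labels <- function(a, b) c(setdiff(a, b), setdiff(b, a))

# Per-edge rate matrices + root distribution for either model, in phylo edge
# order.  `shared = TRUE` means one matrix applies to all edges (NR).
edge_model_for_phylo <- function(params, phy) {
  if (inherits(params, "nr_parameters")) {
    Q <- nr_rate_matrix(params$pi, params$kappa, params$eps_r, params$eps_n)
    list(shared = TRUE, Q = list(Q),
         root_dist = stationary_distribution(Q))
  } else if (inherits(params, "hb_parameters")) {
    bm <- hb_branch_matrices(params, phy)
    list(shared = FALSE, Q = bm$Q, root_dist = bm$root_dist)
  } else stop("params must be nr_parameters or hb_parameters")
}

#' Exhaustive-enumeration log-likelihood (test oracle)
#'
#' Identical contract to [tree_log_likelihood()], computed by brute force:
#' for every site pattern and rate category, sum over all `4^(n-1)`
#' assignments of states to internal nodes the product of the root
#' probability and the per-edge transition probabilities (from the
#' independent R-level [transition_probabilities()] route).  Tractable only
#' for small trees; it exists to certify the pruning implementation.
#'
#' @inheritParams tree_log_likelihood
#' @param max_taxa Refuse larger problems (default 7).
#' @return Log-likelihood.
#' @export
brute_force_log_likelihood <- function(aln, tree, params, max_taxa = 7L) {
  stopifnot(inherits(aln, "nt_alignment"))
  phy <- tree
  n <- length(phy$tip.label)
  if (n > max_taxa) stop("too many taxa for exhaustive enumeration")
  if (!setequal(aln$labels, phy$tip.label))
    stop("alignment taxa and tree leaves differ")
  if (aln$n_sites == 0L) return(0)
  cp <- compress_patterns(aln)
  tp <- tip_partials(cp$patterns, aln$labels, phy$tip.label)
  mod <- edge_model_for_phylo(params, phy)
  tr <- rt_from_phylo(phy)
  rates <- discrete_gamma_rates(params$alpha, params$K)
  K <- length(rates)
  internals <- setdiff(seq_len(rt_nnode_total(tr)), seq_len(n))
  n_int <- length(internals)
  states <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  eds <- rt_postorder_edges(tr)
  edge_of_child <- match(eds[, "child"], phy$edge[, 2L])
  n_pat <- ncol(cp$patterns)
  per_cat <- matrix(0, n_pat, K)
  for (k in seq_len(K)) {
    Pl <- lapply(seq_len(nrow(eds)), function(e) {
      Q <- if (mod$shared) mod$Q[[1L]] else mod$Q[[edge_of_child[e]]]
      transition_probabilities(Q, phy$edge.length[edge_of_child[e]] * rates[k])
    })
    for (p in seq_len(n_pat)) {
      tot <- 0
      for (a in seq_len(nrow(states))) {
        st <- integer(rt_nnode_total(tr))
        st[internals] <- states[a, ]
        w <- mod$root_dist[st[tr$root]]
        for (e in seq_len(nrow(eds))) {
          par <- eds[e, "parent"]; ch <- eds[e, "child"]
          w <- w * if (ch <= n) sum(Pl[[e]][st[par], ] * tp[, p, ch])
                   else Pl[[e]][st[par], st[ch]]
          if (w == 0) break
        }
        tot <- tot + w
      }
      per_cat[p, k] <- log(tot)
    }
  }
  m <- apply(per_cat, 1L, max)
  ll_pat <- m + log(rowSums(exp(per_cat - m))) - log(K)
  sum(cp$weights * ll_pat)
}
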