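# Posterior summaries: root-split posterior, majority-rule consensus,
# branch GC ranking, standardized marginal likelihood, empirical composition
# heterogeneity.

samples_of <- function(x) {
  if (inherits(x, "root_mcmc")) x$samples
  else if (is.list(x) && length(x) && !is.null(x[[1L]]$tree)) x
  else stop("expected a root_mcmc fit or a list of chain samples")
}

#' Posterior distribution over root splits
#'
#' The relative frequency of each canonical root split among the retained
#' samples.  This is a *marginal* summary: it averages over the
#' relationships elsewhere in the tree, and its argmax can legitimately
#' differ from the root shown on the majority-rule consensus tree (a
#' conditional, clade-wise summary).
#'
#' @param x A `root_mcmc` fit or list of chain samples.
#' @return Tibble with `split`, `count`, `probability`, `cumulative`,
#'   sorted by decreasing probability; probabilities sum to 1.
#' @export
root_split_posterior <- function(x) {
  smp <- samples_of(x)
  if (!length(smp)) stop("no samples")
  keys <- vapply(smp, function(s) s$root_split, "")
  tab <- sort(table(keys), decreasing = TRUE)
  out <- tibble::tibble(split = names(tab),
                        count = as.integer(tab),
                        probability = as.numeric(tab) / length(keys))
  out$cumulative <- cumsum(out$probability)
  structure(out, class = c("root_split_posterior", class(out)))
}

# clade keys (non-root nodes incl. tips) of one sample's tree
sample_clades <- function(s) {
  tr <- s$tree
  keys <- rt_clade_keys(tr)
  keys[-tr$root]
}

#' Majority-rule consensus tree
#'
#' The rooted tree containing precisely the rooted clades (descendant
#' leaf-sets) with posterior support strictly greater than 0.5; ties at
#' exactly 0.5 are excluded.  Such clades are automatically mutually
#' compatible, so they nest into a rooted tree, possibly with polytomies
#' (including an unresolved root when no root-adjacent clade clears 0.5).
#' Branch lengths are posterior means over the samples containing the clade;
#' supports are attached as internal node labels.
#'
#' Rooted clades, not unrooted bipartitions, define identity here: the root
#' position is the estimand, so the same unrooted clade on opposite sides of
#' the root counts as two different clades.
#'
#' @param x A `root_mcmc` fit or list of chain samples.
#' @return A `phylo` object (class also `consensus_tree`) with
#'   `node.label` supports and a `clades` tibble attribute
#'   (`clade`, `support`, `mean_length`).
#' @export
majority_rule_consensus <- function(x) {
  smp <- samples_of(x)
  if (!length(smp)) stop("no samples")
  labels <- sort(smp[[1L]]$tree$labels)
  for (s in smp) if (!setequal(s$tree$labels, labels))
    stop("samples have inconsistent taxon sets")
  n_s <- length(smp)
  counts <- new.env(hash = TRUE)
  lensum <- new.env(hash = TRUE)
  for (s in smp) {
    tr <- s$tree
    keys <- rt_clade_keys(tr)
    for (v in seq_len(rt_nnode_total(tr))) {
      if (v == tr$root) next
      k <- keys[v]
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      lensum[[k]] <- (if (is.null(lensum[[k]])) 0 else lensum[[k]]) +
        tr$elen[v]
    }
  }
  keys <- ls(counts)
  support <- vapply(keys, function(k) counts[[k]] / n_s, 0)
  mean_len <- vapply(keys, function(k) lensum[[k]] / counts[[k]], 0)
  keep <- support > 0.5
  keys <- keys[keep]; support <- support[keep]; mean_len <- mean_len[keep]
  sets <- lapply(strsplit(keys, ",", fixed = TRUE), sort)
  sizes <- lengths(sets)
  ord <- order(-sizes)
  sets <- sets[ord]; keys <- keys[ord]
  support <- support[ord]; mean_len <- mean_len[ord]
  # attach each clade to the smallest strictly containing clade (or the root)
  parent <- integer(length(sets))  # 0 = root (full taxon set)
  for (i in seq_along(sets)) {
    parent[i] <- 0L
    for (j in seq_len(i - 1L)) {  # larger-or-equal clades come first
      if (length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]]))
        parent[i] <- j  # later j are smaller: keep the last (smallest) match
    }
  }
  build <- function(children_idx) {
    parts <- vapply(children_idx, function(i) {
      kids <- which(parent == i)
      lab <- if (length(sets[[i]]) == 1L) sets[[i]][1L]
             else sprintf("(%s)%.3f", build(kids), support[i])
      sprintf("%s:%.10g", lab, mean_len[i])
    }, "")
    paste(parts, collapse = ",")
  }
  top <- which(parent == 0L)
  nwk <- sprintf("(%s);", build(top))
  phy <- ape::read.tree(text = nwk)
  cl <- tibble::tibble(clade = keys, support = unname(support),
                       mean_length = unname(mean_len))
  attr(phy, "clades") <- cl
  class(phy) <- c("consensus_tree", "phylo")
  phy
}

#' Rank consensus branches by posterior mean GC content
#'
#' For each branch of a reference (consensus) tree, the posterior mean GC
#' content of its HB composition, averaged over the samples that contain the
#' clade below the branch; samples in which the branch is root-adjacent
#' contribute the GC of their root composition.  Branches are returned in
#' decreasing order (rank 1 = most GC-rich), the ordering used to annotate
#' consensus trees, where high-GC branches clustering near the root is the
#' signature compositional story.
#'
#' @param x A `root_mcmc` HB fit or list of HB chain samples.
#' @param reference A tree whose branches to rank, typically
#'   [majority_rule_consensus()]; defaults to the consensus of `x`.
#' @return Tibble with `clade`, `mean_gc`, `n_samples`, `rank`; clades with
#'   no matching samples get `NA` and are ranked last.
#' @export
rank_branches_by_gc <- function(x, reference = NULL) {
  smp <- samples_of(x)
  if (!length(smp)) stop("no samples")
  if (smp[[1L]]$model != "HB")
    stop("branch GC ranking requires HB samples (per-branch compositions)")
  if (is.null(reference)) reference <- majority_rule_consensus(x)
  ref_keys <- if (!is.null(attr(reference, "clades")))
    attr(reference, "clades")$clade else tree_clades(reference)
  gc_sum <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  gc_n <- stats::setNames(integer(length(ref_keys)), ref_keys)
  for (s in smp) {
    tr <- s$tree
    keys <- rt_clade_keys(tr)
    gc_root <- unname(s$params$pi_root[2L] + s$params$pi_root[3L])
    rk <- c(tr$kid1[tr$root], tr$kid2[tr$root])
    for (v in seq_len(rt_nnode_total(tr))) {
      if (v == tr$root) next
      k <- keys[v]
      if (!k %in% ref_keys) next
      gc <- if (v %in% rk) gc_root else {
        pi_v <- alr_inv(s$params$a_edge[, v])
        unname(pi_v[2L] + pi_v[3L])
      }
      gc_sum[k] <- gc_sum[k] + gc
      gc_n[k] <- gc_n[k] + 1L
    }
  }
  mean_gc <- ifelse(gc_n > 0L, gc_sum / gc_n, NA_real_)
  out <- tibble::tibble(clade = ref_keys, mean_gc = unname(mean_gc),
                        n_samples = unname(gc_n))
  out <- out[order(-ifelse(is.na(out$mean_gc), -Inf, out$mean_gc),
                   out$clade), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Standardized marginal likelihood curve
#'
#' The posterior density of a non-negative scalar (typically `sigma_r` or
#' `sigma_n` of the NR model) divided pointwise by its prior density — the
#' weight of evidence the data carry for each value.  Sampling the prior
#' itself gives a flat curve at 1; a curve near 0 at the origin is evidence
#' against the parameter being 0 (e.g. evidence of non-reversibility for
#' `sigma_n`).  The posterior density is a Gaussian KDE with Silverman
#' bandwidth on the boundary-reflected sample, evaluated on a uniform grid.
#'
#' @param sigma Numeric vector of posterior draws (>= 0), at least 100.
#' @param prior_density Function giving the prior density, or a single
#'   exponential rate (then `dexp(x, rate)` is used).
#' @param n_grid Grid size (default 512) over `[0, 1.1 * max(sigma)]`.
#' @return Tibble (class `sml_curve`) with `sigma`, `posterior`, `prior`,
#'   `ratio`.
#' @export
standardized_marginal_likelihood <- function(sigma, prior_density,
                                             n_grid = 512) {
  sigma <- as.numeric(sigma)
  if (length(sigma) < 100) stop("need at least 100 samples")
  if (any(sigma < 0)) stop("sigma samples must be non-negative")
  if (max(sigma) == min(sigma)) stop("degenerate all-equal samples")
  if (is.numeric(prior_density) && length(prior_density) == 1L) {
    rate <- prior_density
    prior_density <- function(x) stats::dexp(x, rate)
  }
  refl <- c(sigma, -sigma)
  # Silverman bandwidth with n = number of distinct draws, so that
  # duplicating the sample set (doubling every weight) leaves the curve
  # unchanged; thinned MCMC output often contains repeated values
  n_eff <- 2 * length(unique(sigma))
  bw <- 0.9 * min(stats::sd(refl), stats::IQR(refl) / 1.34) * n_eff^(-1 / 5)
  hi <- 1.1 * max(sigma)
  d <- stats::density(refl, bw = bw, from = 0, to = hi, n = n_grid)
  post <- 2 * d$y  # fold the reflected mass back onto [0, Inf)
  pri <- prior_density(d$x)
  out <- tibble::tibble(sigma = d$x, posterior = post, prior = pri,
                        ratio = ifelse(pri > 0, post / pri, NA_real_))
  structure(out, class = c("sml_curve", class(out)))
}

#' Empirical composition heterogeneity of an alignment
#'
#' Per-taxon nucleotide proportions among unambiguous, non-gap sites, and
#' the across-taxa sample standard deviation (divisor `n - 1`) of each
#' proportion.  Large values (e.g. an SD of the guanine proportion well
#' above those of related datasets) indicate compositional heterogeneity
#' that stationary models such as NR cannot accommodate.
#'
#' @param aln An [nt_alignment()] with at least two taxa.
#' @return Tibble with `base` (A, C, G, T), `mean_proportion`, `sd`; the
#'   per-taxon proportions are attached as a tibble attribute
#'   `"proportions"`.
#' @export
empirical_composition_sd <- function(aln) {
  stopifnot(inherits(aln, "nt_alignment"))
  if (length(aln$labels) < 2L) stop("need at least 2 taxa")
  props <- t(apply(aln$seq, 1L, function(row) {
    obs <- row[row %in% NUC]
    if (!length(obs)) stop("taxon with zero unambiguous sites")
    tab <- table(factor(obs, levels = NUC))
    as.numeric(tab) / length(obs)
  }))
  colnames(props) <- NUC
  out <- tibble::tibble(base = NUC,
                        mean_proportion = unname(colMeans(props)),
                        sd = unname(apply(props, 2L, stats::sd)))
  attr(out, "proportions") <- tibble::as_tibble(
    cbind(tibble::tibble(taxon = aln$labels), as.data.frame(props)))
  out
}
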