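#' Read a rooted binary tree from newick
#'
#' Parses a newick string (or file) into an [ape::read.tree()] `phylo` object
#' and validates it as a rooted, strictly binary tree with positive finite
#' branch lengths and unique tip labels — the tree class whose root position
#' the NR and HB models can identify.
#'
#' @param text Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @param file Path to a newick file (used when `text` is `NULL`).
#' @return A validated `phylo` object.
#' @examples
#' tr <- read_rooted_tree("((A:1,B:1):1,C:2);")
#' root_split(tr)
#' @export
read_rooted_tree <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("newick parse error: ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    ape::read.tree(file)
  }
  if (is.null(phy)) stop("newick parse error: malformed tree text")
  validate_rooted_tree(phy)
}

#' Validate a rooted binary tree
#'
#' Checks the invariants the samplers rely on: strict bifurcation everywhere
#' (the root included), unique non-empty tip labels, and positive finite
#' branch lengths; a tree with `n` leaves must have `2n-2` edges.
#'
#' @param phy A `phylo` object.
#' @return `phy`, invisibly-validated (returned unchanged).
#' @export
validate_rooted_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip label: ",
         phy$tip.label[anyDuplicated(phy$tip.label)])
  if (is.null(phy$edge.length))
    stop("tree must carry branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length <= 0))
    stop("non-positive or non-finite branch length at edge ",
         which(!is.finite(phy$edge.length) | phy$edge.length <= 0)[1L])
  rt_from_phylo(phy)  # full binary/rootedness validation
  phy
}

#' Write a rooted tree as newick
#'
#' Branch lengths are always written, with 10 significant digits; internal
#' node labels (if present, e.g. consensus supports) are preserved.
#'
#' @param phy A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string (invisibly when writing to file).
#' @export
write_rooted_tree <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root split of a rooted tree
#'
#' The bipartition of the taxon set induced by deleting the root — the
#' marginal estimand of root inference.  Canonical form: the side containing
#' the lexicographically smallest label is listed first.
#'
#' @param phy A rooted binary `phylo` object.
#' @return An object of class `root_split`: a list with elements `side1`,
#'   `side2` (sorted character vectors) and `key` (the canonical
#'   `"A,B|C,D"` string).
#' @examples
#' root_split(read_rooted_tree("((A:1,B:1):1,(C:1,D:1):1);"))$key
#' @export
root_split <- function(phy) {
  tr <- rt_from_phylo(phy)
  key <- rt_root_split_key(tr)
  sides <- strsplit(key, "|", fixed = TRUE)[[1L]]
  structure(list(side1 = strsplit(sides[1L], ",", fixed = TRUE)[[1L]],
                 side2 = strsplit(sides[2L], ",", fixed = TRUE)[[1L]],
                 key = key),
            class = "root_split")
}

#' @export
print.root_split <- function(x, ...) {
  cat("Root split: {", paste(x$side1, collapse = ", "), "} | {",
      paste(x$side2, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Enumerate all rootings of an unrooted tree
#'
#' Given an unrooted binary tree (basal trifurcation, as produced by
#' [ape::unroot()]), returns the `2n-3` rooted trees obtained by placing the
#' root at the midpoint of each edge.  Under a stationary reversible model all
#' of these have the same likelihood (the pulley principle); under NR with
#' non-zero non-reversible perturbations, or HB with unequal compositions,
#' they generally do not — which is what makes the root inferable.
#'
#' @param phy An unrooted binary `phylo` object with `n >= 3` tips.
#' @return A list of `2n-3` rooted `phylo` objects with pairwise-distinct
#'   root splits.
#' @export
enumerate_rootings <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  n <- length(phy$tip.label)
  if (n < 3L) stop("need at least 3 tips to enumerate rootings")
  if (ape::is.rooted(phy)) stop("input must be unrooted (basal trifurcation)")
  if (n + phy$Nnode != 2L * n - 2L)
    stop("input must be a binary unrooted tree")
  # Root arbitrarily on the first edge, then re-root on every unrooted edge.
  tr0 <- rt_from_unrooted_phylo(phy)
  # unrooted edges: every non-root node owns one, except the two root
  # children share a single unrooted edge: drop one of them.
  drop_child <- tr0$kid2[tr0$root]
  owners <- setdiff(seq_len(rt_nnode_total(tr0)), c(tr0$root, drop_child))
  lapply(owners, function(v) {
    rt_to_phylo(rt_reroot(tr0, v, frac = 0.5)$tree)
  })
}

# Root an unrooted phylo (basal trifurcation) by inserting a root at the
# midpoint of the first basal child's edge.
rt_from_unrooted_phylo <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode  # = 2n - 2
  par <- integer(nn + 1L); kid <- vector("list", nn + 1L)
  elen <- rep(NA_real_, nn + 1L)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    par[v] <- p; elen[v] <- phy$edge.length[i]
    kid[[p]] <- c(kid[[p]], v)
  }
  base <- setdiff(seq_len(nn), phy$edge[, 2L])
  if (length(base) != 1L || length(kid[[base]]) != 3L)
    stop("input must have a single basal trifurcation")
  # new root above the first basal child
  newroot <- nn + 1L
  v <- kid[[base]][1L]
  kid[[base]] <- kid[[base]][-1L]
  kid[[newroot]] <- c(v, base)
  half <- elen[v] / 2
  par[v] <- newroot; par[base] <- newroot
  elen[v] <- half; elen[base] <- half
  kid1 <- integer(nn + 1L); kid2 <- integer(nn + 1L)
  for (w in seq_len(nn + 1L)) {
    if (length(kid[[w]]) == 2L) { kid1[w] <- kid[[w]][1L]; kid2[w] <- kid[[w]][2L] }
    else if (length(kid[[w]]) != 0L) stop("tree is not binary at node ", w)
  }
  rt_validate(rt_new(n, phy$tip.label, par, kid1, kid2, elen, newroot))
}

#' Random rooted binary tree
#'
#' Topology uniform over rooted binary shapes; branch lengths i.i.d. from
#' `rlen` (default exponential with mean 0.1 substitutions/site, matching the
#' branch-length prior used by the samplers).
#'
#' @param n Number of tips (labels `t1..tn` unless given).
#' @param labels Optional tip labels.
#' @param rlen Function `k -> k` positive branch lengths.
#' @return A rooted binary `phylo` object.
#' @export
random_rooted_tree <- function(n, labels = paste0("t", seq_len(n)),
                               rlen = function(k) stats::rexp(k, rate = 10)) {
  rt_to_phylo(rt_random(labels, rlen))
}

#' Rooted clades of a tree
#'
#' Descendant leaf-sets of every non-root node (tips included), as canonical
#' comma-joined keys.  These rooted clades — not unrooted bipartitions — are
#' the units of consensus-tree construction, because the root position is
#' itself the estimand.
#'
#' @param phy A rooted binary `phylo` object.
#' @return Character vector of clade keys.
#' @export
tree_clades <- function(phy) {
  tr <- rt_from_phylo(phy)
  keys <- rt_clade_keys(tr)
  keys[-tr$root]
}
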