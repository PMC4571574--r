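# Internal rooted-tree representation used by the sampler.
#
# Nodes are integer ids 1..(2n-1): tips are 1..n (fixed, matching `labels`),
# internal nodes occupy the remaining ids in arbitrary order.  Each non-root
# node v owns the edge v -> par[v] and its length elen[v].  The structure is
# strictly binary: the root and every internal node have exactly two children.

rt_new <- function(ntip, labels, par, kid1, kid2, elen, root) {
  structure(list(ntip = ntip, labels = labels, par = par,
                 kid1 = kid1, kid2 = kid2, elen = elen, root = root),
            class = "rtree")
}

rt_nnode_total <- function(tr) 2L * tr$ntip - 1L

# Full structural validation; called after every tree-modifying proposal in
# tests and cheaply assertable anywhere.
rt_validate <- function(tr, check_lengths = TRUE, allow_zero = FALSE) {
  n <- tr$ntip
  nn <- 2L * n - 1L
  stopifnot(length(tr$par) == nn, length(tr$kid1) == nn,
            length(tr$kid2) == nn, length(tr$elen) == nn)
  if (anyDuplicated(tr$labels) || any(!nzchar(tr$labels)))
    stop("tip labels must be unique non-empty strings")
  if (tr$par[tr$root] != 0L) stop("root must have no parent")
  is_tip <- seq_len(nn) <= n
  if (any(tr$kid1[is_tip] != 0L) || any(tr$kid2[is_tip] != 0L))
    stop("tips must be leaves")
  ints <- which(!is_tip)
  if (any(tr$kid1[ints] == 0L) || any(tr$kid2[ints] == 0L))
    stop("internal node without two children (tree must be binary)")
  # parent/child consistency and connectivity
  for (v in seq_len(nn)) {
    if (v == tr$root) next
    p <- tr$par[v]
    if (p < 1L || p > nn || p <= n) stop("invalid parent pointer")
    if (tr$kid1[p] != v && tr$kid2[p] != v)
      stop("parent does not list node among its children")
  }
  if (length(rt_preorder(tr)) != nn) stop("tree is not connected")
  if (check_lengths) {
    el <- tr$elen[-tr$root]
    bad <- !is.finite(el) | (if (allow_zero) el < 0 else el <= 0)
    if (any(bad))
      stop("all branch lengths must be positive and finite")
  }
  invisible(tr)
}

rt_preorder <- function(tr) {
  nn <- rt_nnode_total(tr)
  out <- integer(nn); stack <- integer(nn)
  top <- 1L; stack[1L] <- tr$root; k <- 0L
  while (top > 0L) {
    v <- stack[top]; top <- top - 1L
    k <- k + 1L; out[k] <- v
    if (tr$kid1[v] != 0L) {
      top <- top + 1L; stack[top] <- tr$kid1[v]
      top <- top + 1L; stack[top] <- tr$kid2[v]
    }
  }
  out[seq_len(k)]
}

# Postorder edge matrix (parent, child): every child appears before the edge
# to its own parent is visited, as the pruning recursion requires.
rt_postorder_edges <- function(tr) {
  ord <- rev(rt_preorder(tr))
  ord <- ord[ord != tr$root]
  cbind(parent = tr$par[ord], child = ord)
}

# Tip ids below each node, as a list indexed by node id.
rt_tips_under <- function(tr) {
  nn <- rt_nnode_total(tr)
  res <- vector("list", nn)
  for (v in rev(rt_preorder(tr))) {
    if (tr$kid1[v] == 0L) res[[v]] <- v
    else res[[v]] <- c(res[[tr$kid1[v]]], res[[tr$kid2[v]]])
  }
  res
}

clade_key_from_labels <- function(labs) paste(sort(labs), collapse = ",")

# Canonical clade key (sorted tip labels) for every non-root node.
rt_clade_keys <- function(tr) {
  tu <- rt_tips_under(tr)
  nn <- rt_nnode_total(tr)
  keys <- character(nn)
  for (v in seq_len(nn)) keys[v] <- clade_key_from_labels(tr$labels[tu[[v]]])
  keys
}

rt_root_split_key <- function(tr) {
  kids <- c(tr$kid1[tr$root], tr$kid2[tr$root])
  tu <- rt_tips_under(tr)
  s1 <- sort(tr$labels[tu[[kids[1L]]]])
  s2 <- sort(tr$labels[tu[[kids[2L]]]])
  canonical_split_key(s1, s2)
}

canonical_split_key <- function(s1, s2) {
  if (min(s2) < min(s1)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  paste(paste(s1, collapse = ","), paste(s2, collapse = ","), sep = "|")
}

## --- conversion to/from ape ---------------------------------------------

rt_from_phylo <- function(phy, allow_zero = FALSE, check_lengths = TRUE) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  n <- length(phy$tip.label)
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  nn <- n + phy$Nnode
  if (nn != 2L * n - 1L)
    stop("tree must be rooted and strictly binary (", nn, " nodes for ", n,
         " tips)")
  par <- integer(nn); kid1 <- integer(nn); kid2 <- integer(nn)
  elen <- rep(NA_real_, nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    par[v] <- p
    elen[v] <- phy$edge.length[i]
    if (kid1[p] == 0L) kid1[p] <- v
    else if (kid2[p] == 0L) kid2[p] <- v
    else stop("node ", p, " has more than two children; tree must be binary")
  }
  root <- setdiff(seq_len(nn), phy$edge[, 2L])
  if (length(root) != 1L) stop("could not identify a unique root")
  tr <- rt_new(n, phy$tip.label, par, kid1, kid2, elen, as.integer(root))
  rt_validate(tr, check_lengths = check_lengths, allow_zero = allow_zero)
}

rt_to_phylo <- function(tr) {
  n <- tr$ntip
  nn <- 2L * n - 1L
  # renumber internals in preorder so the root becomes n+1 (ape convention)
  ord <- rt_preorder(tr)
  newid <- integer(nn)
  newid[seq_len(n)] <- seq_len(n)
  k <- n
  for (v in ord) if (v > n) { k <- k + 1L; newid[v] <- k }
  edge <- matrix(0L, nn - 1L, 2L)
  elen <- numeric(nn - 1L)
  i <- 0L
  for (v in ord) {
    if (v == tr$root) next
    i <- i + 1L
    edge[i, ] <- c(newid[tr$par[v]], newid[v])
    elen[i] <- tr$elen[v]
  }
  phy <- list(edge = edge, edge.length = elen, Nnode = n - 1L,
              tip.label = tr$labels)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

## --- tree surgery ---------------------------------------------------------

# Nearest-neighbour interchange around internal node v (v != root): swap one
# child of v with v's sibling.  Edge lengths and edge identities travel with
# their child nodes.  Returns list(tree, swapped_up, swapped_down, at_root).
rt_nni <- function(tr, v, which_child = 1L) {
  if (v <= tr$ntip || v == tr$root) stop("NNI needs an internal non-root node")
  u <- tr$par[v]
  w <- if (tr$kid1[u] == v) tr$kid2[u] else tr$kid1[u]  # sibling of v
  x <- if (which_child == 1L) tr$kid1[v] else tr$kid2[v]
  # swap x and w
  if (tr$kid1[u] == w) tr$kid1[u] <- x else tr$kid2[u] <- x
  if (tr$kid1[v] == x) tr$kid1[v] <- w else tr$kid2[v] <- w
  tr$par[x] <- u
  tr$par[w] <- v
  list(tree = tr, swapped_up = x, swapped_down = w, at_root = (u == tr$root))
}

# Candidate NNI centres: internal, non-root nodes.
rt_nni_candidates <- function(tr) {
  nn <- rt_nnode_total(tr)
  setdiff((tr$ntip + 1L):nn, tr$root)
}

# Re-root on the edge owned by node v (v -> par(v)), placing the root so that
# a fraction `frac` of the combined unrooted edge length lies on v's side.
# When v is already a child of the root this just re-partitions the two root
# edges.  Otherwise the old root node is deleted (its two edges merge) and its
# id is reused for the new root.  Returns list(tree, flipped = integer map
# old_child -> new_child for edges whose owning node changed, merged = child
# id now owning the merged old-root edge, old_root_children, new_root_children).
rt_reroot <- function(tr, v, frac = 0.5) {
  r <- tr$root
  if (v == r) stop("cannot re-root on the root itself")
  u <- tr$par[v]
  if (u == r) {
    sib <- if (tr$kid1[r] == v) tr$kid2[r] else tr$kid1[r]
    tot <- tr$elen[v] + tr$elen[sib]
    tr$elen[v] <- frac * tot
    tr$elen[sib] <- (1 - frac) * tot
    return(list(tree = tr, flipped = NULL, merged = NA_integer_,
                old_root_children = c(v, sib), new_root_children = c(v, sib)))
  }
  # path v = p0, p1, ..., pk = r
  path <- v
  w <- v
  while (w != r) { w <- tr$par[w]; path <- c(path, w) }
  k <- length(path) - 1L  # k >= 2 here
  orig_par <- tr$par; orig_len <- tr$elen
  orig_k1 <- tr$kid1; orig_k2 <- tr$kid2
  c_node <- path[k]  # old-root child on the path
  d_node <- if (orig_k1[r] == c_node) orig_k2[r] else orig_k1[r]
  # merge the two old root edges into one owned by d
  tr$par[d_node] <- c_node
  tr$elen[d_node] <- orig_len[c_node] + orig_len[d_node]
  # reverse the path: p_i (1 <= i <= k-1) becomes a child of p_{i-1}
  for (i in seq_len(k - 1L)) {
    p_i <- path[i + 1L]
    below <- path[i]       # new parent of p_i
    above <- if (i + 2L <= k + 1L) path[i + 2L] else NA_integer_  # old parent
    # children of p_i: drop `below`, add old parent (or d at the top)
    newkid <- if (i == k - 1L) d_node else above
    if (tr$kid1[p_i] == below) tr$kid1[p_i] <- newkid
    else if (tr$kid2[p_i] == below) tr$kid2[p_i] <- newkid
    else stop("internal error in rt_reroot: path child mismatch")
    if (i >= 2L) {
      tr$par[p_i] <- below
      tr$elen[p_i] <- orig_len[below]
    }
  }
  # new root reuses id r, with children v and u = p1
  p1 <- path[2L]
  tot <- orig_len[v]
  tr$kid1[r] <- v; tr$kid2[r] <- p1
  tr$par[r] <- 0L; tr$elen[r] <- NA_real_
  tr$par[v] <- r;  tr$elen[v] <- frac * tot
  tr$par[p1] <- r; tr$elen[p1] <- (1 - frac) * tot
  flipped <- if (k >= 3L)
    stats::setNames(path[3L:(k)], path[2L:(k - 1L)]) else NULL
  # flipped: edge formerly owned by p_{i} (old child end) is now owned by
  # p_{i+1}; names are old owners, values new owners.
  list(tree = tr, flipped = flipped, merged = d_node,
       old_root_children = c(c_node, d_node), new_root_children = c(v, p1))
}

# Uniform random rooted binary topology on the given labels, by sequential
# random attachment; branch lengths drawn from `rlen`.  Each new tip attaches
# either below one of the 2t-2 existing edges or above the current root
# (2t-1 equiprobable positions), which makes the topology uniform over the
# (2n-3)!! rooted binary shapes.
rt_random <- function(labels, rlen = function(k) stats::rexp(k, rate = 10)) {
  n <- length(labels)
  stopifnot(n >= 2L)
  nn <- 2L * n - 1L
  par <- integer(nn); kid1 <- integer(nn); kid2 <- integer(nn)
  elen <- rep(NA_real_, nn)
  next_int <- n + 1L
  root <- next_int; next_int <- next_int + 1L
  par[1L] <- root; par[2L] <- root
  kid1[root] <- 1L; kid2[root] <- 2L
  pool <- c(1L, 2L)  # nodes owning an attachable edge (root handled apart)
  for (tip in seq(3L, length.out = n - 2L)) {
    pick <- sample.int(length(pool) + 1L, 1L)
    newint <- next_int; next_int <- next_int + 1L
    if (pick > length(pool)) {  # attach above the current root
      kid1[newint] <- root; kid2[newint] <- tip
      par[root] <- newint; par[tip] <- newint
      pool <- c(pool, tip, root)
      root <- newint
    } else {
      e <- pool[pick]
      p <- par[e]
      if (kid1[p] == e) kid1[p] <- newint else kid2[p] <- newint
      par[newint] <- p
      kid1[newint] <- e; kid2[newint] <- tip
      par[e] <- newint; par[tip] <- newint
      pool <- c(pool, tip, newint)
    }
  }
  elen[-root] <- rlen(nn - 1L)
  tr <- rt_new(n, labels, par, kid1, kid2, elen, root)
  rt_validate(tr)
}
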