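# Summaries are tested on hand-built sample lists: each fake chain sample
# only needs a tree (internal form) and, for GC ranking, HB parameters.

fake_sample <- function(newick, model = "NR", pi_root = rep(0.25, 4),
                        a_edge = NULL) {
  tr <- phyloroot:::rt_from_phylo(read_rooted_tree(newick))
  s <- list(iteration = 1L, ll = 0, lp = 0, tree = tr,
            root_split = phyloroot:::rt_root_split_key(tr), model = model)
  if (model == "HB") {
    nn <- 2L * tr$ntip - 1L
    if (is.null(a_edge)) a_edge <- matrix(0, 3, nn)
    s$params <- list(rho = rep(1, 6),
                     pi_root = composition_vector(pi_root),
                     s = 0.5, alpha = 1, a_edge = a_edge)
  }
  s
}

test_that("root split posterior counts canonical splits and normalizes", {
  s1 <- fake_sample("((A:1,B:1):1,(C:1,D:1):1);")
  s2 <- fake_sample("(((A:1,B:1):1,C:1):1,D:1);")
  rsp <- root_split_posterior(c(rep(list(s1), 7), rep(list(s2), 3)))
  expect_equal(rsp$split, c("A,B|C,D", "A,B,C|D"))
  expect_equal(rsp$probability, c(0.7, 0.3))
  expect_equal(sum(rsp$probability), 1, tolerance = 1e-12)
  expect_equal(rsp$cumulative, c(0.7, 1.0))
  one <- root_split_posterior(rep(list(s1), 10))
  expect_equal(one$probability, 1.0)
})

test_that("majority-rule consensus contains exactly the clades above 0.5", {
  # 60/40 mix sharing clade {A,B}; the conflicting 0.4-clades must be absent
  s1 <- fake_sample("(((A:1,B:1):1,C:1):1,D:1);")   # clades AB, ABC
  s2 <- fake_sample("(((A:1,B:1):1,D:1):1,C:1);")   # clades AB, ABD
  cons <- majority_rule_consensus(c(rep(list(s1), 6), rep(list(s2), 4)))
  cl <- attr(cons, "clades")
  expect_true("A,B" %in% cl$clade)
  expect_equal(cl$support[cl$clade == "A,B"], 1.0)
  expect_true("A,B,C" %in% cl$clade)
  expect_equal(cl$support[cl$clade == "A,B,C"], 0.6)
  expect_false("A,B,D" %in% cl$clade)
  # exact 0.5 ties are excluded
  cons2 <- majority_rule_consensus(c(rep(list(s1), 5), rep(list(s2), 5)))
  cl2 <- attr(cons2, "clades")
  expect_false("A,B,C" %in% cl2$clade)
  expect_false("A,B,D" %in% cl2$clade)
  expect_true("A,B" %in% cl2$clade)
})

test_that("identical samples give their own tree with unit supports and
           exact branch lengths", {
  s <- fake_sample("(((A:1,B:2):3,C:4):5,D:6);")
  cons <- majority_rule_consensus(rep(list(s), 8))
  cl <- attr(cons, "clades")
  expect_true(all(cl$support == 1))
  expect_setequal(cl$clade, c("A", "B", "C", "D", "A,B", "A,B,C"))
  expect_equal(cl$mean_length[cl$clade == "A,B"], 3)
  expect_equal(root_split(cons)$key, "A,B,C|D")
})

test_that("the consensus root can disagree with the modal root split", {
  # Three rootings sharing clade {C,D}: the modal root split pairs {A,B}
  # against it, but {A,B} never reaches majority support, so the consensus
  # root is an unresolved trifurcation — the split with most marginal
  # support is absent from the conditional (consensus) summary.
  s1 <- fake_sample("((A:1,B:1):1,(C:1,D:1):1);")  # split A,B|C,D
  s2 <- fake_sample("(((C:1,D:1):1,A:1):1,B:1);")  # split A,C,D|B
  s3 <- fake_sample("(((C:1,D:1):1,B:1):1,A:1);")  # split B,C,D|A
  samples <- c(rep(list(s1), 4), rep(list(s2), 3), rep(list(s3), 3))
  rsp <- root_split_posterior(samples)
  expect_equal(rsp$split[1], "A,B|C,D")
  expect_equal(rsp$probability[1], 0.4)
  cons <- majority_rule_consensus(samples)
  cl <- attr(cons, "clades")
  expect_true("C,D" %in% cl$clade)            # support 1.0
  expect_false("A,B" %in% cl$clade)           # modal split side missing
  rt_root <- length(cons$tip.label) + 1L
  expect_equal(sum(cons$edge[, 1] == rt_root), 3L)  # unresolved root
})

test_that("branch GC ranking averages per-clade compositions and uses the
           root composition on root-adjacent branches", {
  nwk <- "(((A:1,B:1):1,C:1):1,D:1);"
  tr <- phyloroot:::rt_from_phylo(read_rooted_tree(nwk))
  keys <- phyloroot:::rt_clade_keys(tr)
  nn <- 2L * tr$ntip - 1L
  mk <- function(gc_by_clade, gc_root) {
    a <- matrix(0, 3, nn)
    for (v in seq_len(nn)) {
      k <- keys[v]
      if (k %in% names(gc_by_clade)) {
        gc <- gc_by_clade[[k]]
        a[, v] <- phyloroot:::alr(c((1 - gc) / 2, gc / 2, gc / 2,
                                    (1 - gc) / 2))
      }
    }
    pr <- c((1 - gc_root) / 2, gc_root / 2, gc_root / 2, (1 - gc_root) / 2)
    fake_sample(nwk, model = "HB", pi_root = pr, a_edge = a)
  }
  # non-root-adjacent edges: A, B, AB; root-adjacent: ABC and D
  s1 <- mk(c(A = 0.6, B = 0.2, "A,B" = 0.4), gc_root = 0.3)
  s2 <- mk(c(A = 0.8, B = 0.2, "A,B" = 0.4), gc_root = 0.5)
  rk <- rank_branches_by_gc(list(s1, s2),
                            reference = read_rooted_tree(nwk))
  gc_of <- setNames(rk$mean_gc, rk$clade)
  expect_equal(gc_of[["A"]], 0.7, tolerance = 1e-10)       # (0.6+0.8)/2
  expect_equal(gc_of[["B"]], 0.2, tolerance = 1e-10)
  expect_equal(gc_of[["A,B"]], 0.4, tolerance = 1e-10)
  expect_equal(gc_of[["A,B,C"]], 0.4, tolerance = 1e-10)   # root mean
  expect_equal(gc_of[["D"]], 0.4, tolerance = 1e-10)       # root mean
  expect_equal(rk$clade[1], "A")  # rank 1 = most GC rich
  # duplicating the sample set leaves the means unchanged
  rk2 <- rank_branches_by_gc(list(s1, s2, s1, s2),
                             reference = read_rooted_tree(nwk))
  expect_equal(rk2$mean_gc, rk$mean_gc, tolerance = 1e-12)
})

test_that("standardized marginal likelihood is ~1 under prior sampling and
           invariant to duplicating samples", {
  set.seed(41)
  x <- rexp(10000, 4)
  curve <- standardized_marginal_likelihood(x, prior_density = 4)
  mid <- curve$ratio[curve$sigma > quantile(x, 0.02) &
                     curve$sigma < quantile(x, 0.95)]
  expect_lt(max(abs(mid - 1)), 0.2)
  curve2 <- standardized_marginal_likelihood(c(x, x), prior_density = 4)
  expect_equal(curve2$ratio, curve$ratio, tolerance = 1e-9)
  # posterior concentrated away from 0 -> ratio near 0 at the origin
  y <- rnorm(5000, 2, 0.2)
  curve3 <- standardized_marginal_likelihood(y, prior_density = 1)
  expect_lt(curve3$ratio[1], 0.05)
  expect_error(standardized_marginal_likelihood(rep(1, 500), 1),
               "degenerate")
})

test_that("empirical composition SD matches hand computations and ignores
           gaps and ambiguity codes", {
  same <- nt_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(empirical_composition_sd(same)$sd, rep(0, 4))
  two <- nt_alignment(c(a = "GGGG", b = "AAAA"))
  res <- empirical_composition_sd(two)
  expect_equal(res$sd[res$base == "G"], sd(c(1, 0)))  # 0.7071...
  expect_equal(res$sd[res$base == "A"], sd(c(0, 1)))
  # hand-computed 4-taxon fixture with gaps/ambiguity excluded
  aln <- nt_alignment(c(t1 = "AACG-N", t2 = "CCGGTR", t3 = "ACGTAC",
                        t4 = "GGGGGG"))
  props <- attr(empirical_composition_sd(aln), "proportions")
  expect_equal(props$A[props$taxon == "t1"], 2 / 4)  # 4 unambiguous sites
  expect_equal(props$G[props$taxon == "t2"], 2 / 5)  # R excluded
  expect_equal(props$G[props$taxon == "t4"], 1)
  byhand <- apply(cbind(c(2, 0, 2, 0) / c(4, 5, 6, 6),
                        c(1, 2, 2, 0) / c(4, 5, 6, 6),
                        c(1, 2, 1, 6) / c(4, 5, 6, 6),
                        c(0, 1, 1, 0) / c(4, 5, 6, 6)), 2, sd)
  expect_equal(empirical_composition_sd(aln)$sd, byhand, tolerance = 1e-12)
})
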