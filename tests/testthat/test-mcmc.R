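test_that("branch-length multiplier reports the exact log Hastings ratio", {
  set.seed(81)
  tr <- phyloroot:::rt_from_phylo(random_rooted_tree(5))
  st <- phyloroot:::state_from_prior(tr, "NR", prior_spec(), 1L)
  sc <- mcmc_options()$scales
  for (i in 1:20) {
    prop <- phyloroot:::propose_brlen(st, sc)
    changed <- which(prop$state$tr$elen != st$tr$elen)
    expect_length(changed, 1L)
    expect_equal(prop$log_hastings,
                 log(prop$state$tr$elen[changed] / st$tr$elen[changed]),
                 tolerance = 1e-12)
  }
})

test_that("rooted NNI preserves the leaf set, edge count and validity", {
  set.seed(82)
  for (i in 1:30) {
    tr <- phyloroot:::rt_from_phylo(random_rooted_tree(sample(4:8, 1)))
    st <- phyloroot:::state_from_prior(tr, "NR", prior_spec(), 1L)
    prop <- phyloroot:::propose_nni(st, mcmc_options()$scales)
    t2 <- prop$state$tr
    expect_silent(phyloroot:::rt_validate(t2))
    expect_identical(sort(t2$labels), sort(tr$labels))
    expect_equal(sum(t2$kid1 != 0), tr$ntip - 1L)  # n-1 internal nodes
    expect_equal(sum(!is.na(t2$elen)), 2L * tr$ntip - 2L)
  }
})

test_that("re-rooting preserves total branch length and tree validity", {
  set.seed(83)
  for (i in 1:30) {
    tr <- phyloroot:::rt_from_phylo(random_rooted_tree(sample(4:8, 1)))
    st <- phyloroot:::state_from_prior(tr, "NR", prior_spec(), 1L)
    prop <- phyloroot:::propose_reroot(st, mcmc_options()$scales)
    t2 <- prop$state$tr
    expect_silent(phyloroot:::rt_validate(t2))
    expect_equal(sum(t2$elen, na.rm = TRUE), sum(tr$elen, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("HB states keep exactly 2n-4 branch compositions under topology
           moves", {
  set.seed(84)
  n_comp <- function(s) {
    tr <- s$tr
    rk <- c(tr$kid1[tr$root], tr$kid2[tr$root])
    elig <- setdiff(seq_len(2L * tr$ntip - 1L), c(tr$root, rk))
    sum(!is.na(s$a_edge[1L, elig]))
  }
  tr <- phyloroot:::rt_from_phylo(random_rooted_tree(7))
  st <- phyloroot:::state_from_prior(tr, "HB", prior_spec(), 1L)
  sc <- mcmc_options()$scales
  expect_equal(n_comp(st), 2L * 7L - 4L)
  for (i in 1:60) {
    prop <- if (i %% 2 == 0) phyloroot:::propose_nni(st, sc)
            else phyloroot:::propose_reroot(st, sc)
    st <- prop$state
    expect_equal(n_comp(st), 2L * 7L - 4L)
  }
})

test_that("runs are bit-reproducible given the seed", {
  set.seed(1)
  tree <- random_rooted_tree(4)
  aln <- simulate_alignment(tree, nr_parameters(kappa = 2), 60, seed = 3)
  opt <- mcmc_options(n_iter = 400, burnin = 0.25, thin = 5)
  f1 <- run_mcmc(aln, "NR", options = opt, K = 1, seed = 42)
  f2 <- run_mcmc(aln, "NR", options = opt, K = 1, seed = 42)
  expect_identical(f1$trace, f2$trace)
  f3 <- run_mcmc(aln, "NR", options = opt, K = 1, seed = 43)
  expect_false(identical(f1$trace$log_likelihood, f3$trace$log_likelihood))
})

test_that("constant-likelihood runs leave the likelihood at zero and sample
           finite priors", {
  aln0 <- empty_alignment(c("A", "B", "C", "D"))
  fit <- run_mcmc(aln0, "HB", options = mcmc_options(n_iter = 2000,
                                                     burnin = 0.25,
                                                     thin = 5),
                  K = 1, seed = 9)
  expect_true(all(fit$trace$log_likelihood == 0))
  expect_true(all(is.finite(fit$trace$log_prior)))
  expect_gt(min(fit$acceptance$rate, na.rm = TRUE), 0)
})

test_that("tidy and glance summarize a fit", {
  set.seed(2)
  tree <- random_rooted_tree(4)
  aln <- simulate_alignment(tree, nr_parameters(kappa = 2), 50, seed = 4)
  fit <- run_mcmc(aln, "NR", options = mcmc_options(n_iter = 600,
                                                    burnin = 0.25, thin = 5),
                  K = 1, seed = 11)
  td <- tidy(fit)
  expect_true(all(c("kappa", "alpha", "sigma_r", "sigma_n") %in% td$term))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$model, "NR")
  expect_equal(gl$n_taxa, 4L)
  expect_gt(gl$ess_log_likelihood, 1)
})

test_that("plot methods return ggplot objects", {
  s1 <- list(iteration = 1L, ll = 0, lp = 0,
             tree = phyloroot:::rt_from_phylo(
               read_rooted_tree("((A:1,B:1):1,C:1);")),
             root_split = "A,B|C", model = "NR")
  rsp <- root_split_posterior(rep(list(s1), 5))
  expect_s3_class(ggplot2::autoplot(rsp), "ggplot")
  curve <- standardized_marginal_likelihood(rexp(500, 4), 4)
  expect_s3_class(ggplot2::autoplot(curve), "ggplot")
})

test_that("posterior support for the true root split grows with site count
           under NR data with non-reversible signal", {
  set.seed(5)
  tree <- read_rooted_tree(paste0("(((A:0.15,B:0.15):0.3,C:0.4):0.3,",
                                  "((D:0.15,E:0.15):0.3,F:0.4):0.3);"))
  p <- nr_parameters(pi = c(0.35, 0.2, 0.25, 0.2), kappa = 3,
                     eps_r = rnorm(6, 0, 0.3), eps_n = rnorm(12, 0, 0.6),
                     sigma_r = 0.3, sigma_n = 0.6, alpha = 1, K = 1)
  true_split <- root_split(tree)$key
  med_pp <- vapply(c(100, 1000, 10000), function(ns) {
    pp <- vapply(1:5, function(sd) {
      aln <- simulate_alignment(tree, p, ns, seed = 40 + sd)
      fit <- run_mcmc(aln, "NR",
                      options = mcmc_options(n_iter = 12000, burnin = 0.25,
                                             thin = 10),
                      K = 1, seed = sd)
      rsp <- root_split_posterior(fit)
      tp <- rsp$probability[rsp$split == true_split]
      if (length(tp)) tp else 0
    }, 0)
    median(pp)
  }, 0)
  expect_true(all(diff(med_pp) > 0))
})
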