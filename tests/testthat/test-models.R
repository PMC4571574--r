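test_that("HKY85 with uniform composition and kappa 1 is Jukes-Cantor", {
  Q <- hky_rate_matrix(rep(0.25, 4), 1)
  expect_equal(unname(Q[row(Q) != col(Q)]), rep(1 / 3, 12), tolerance = 1e-12)
  expect_equal(unname(diag(Q)), rep(-1, 4), tolerance = 1e-12)
})

test_that("HKY85 stationary distribution is its composition and transition
           ratios follow the definition", {
  set.seed(2)
  for (i in 1:20) {
    pi <- random_composition()
    kappa <- exp(rnorm(1))
    Q <- hky_rate_matrix(pi, kappa)
    expect_equal(unname(stationary_distribution(Q)), unname(pi),
                 tolerance = 1e-10)
    # q_AG / q_AC = (pi_G * kappa) / pi_C regardless of normalization
    expect_equal(Q["A", "G"] / Q["A", "C"], unname(pi["G"] * kappa / pi["C"]),
                 tolerance = 1e-12)
  }
})

test_that("every constructed rate matrix has zero row sums, non-negative
           off-diagonals and unit mean rate", {
  set.seed(3)
  for (i in 1:25) {
    Q <- switch(1 + i %% 3,
                hky_rate_matrix(random_composition(), exp(rnorm(1))),
                gtr_rate_matrix(rexp(6) + 0.1, random_composition()),
                nr_rate_matrix(random_composition(), exp(rnorm(1)),
                               rnorm(6, 0, 0.4), rnorm(12, 0, 0.4)))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
    st <- stationary_distribution(Q)
    expect_equal(-sum(st * diag(Q)), 1, tolerance = 1e-10)
  }
})

test_that("GTR satisfies detailed balance; rho (1,2,1,1,2,1) is HKY kappa 2", {
  set.seed(4)
  for (i in 1:10) {
    pi <- random_composition()
    Q <- gtr_rate_matrix(rexp(6) + 0.1, pi)
    flow <- pi * Q  # pi_i q_ij
    expect_equal(flow, t(flow), tolerance = 1e-12)
  }
  expect_equal(gtr_rate_matrix(c(1, 2, 1, 1, 2, 1), rep(0.25, 4)),
               hky_rate_matrix(rep(0.25, 4), 2), tolerance = 1e-12)
  expect_equal(gtr_rate_matrix(rep(1, 6), rep(0.25, 4)),
               hky_rate_matrix(rep(0.25, 4), 1), tolerance = 1e-12)
})

test_that("NR with zero perturbations is HKY; eps_r alone stays reversible;
           eps_n breaks detailed balance and matches the literal formula", {
  set.seed(5)
  pi <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(nr_rate_matrix(pi, 2), hky_rate_matrix(pi, 2),
               tolerance = 1e-12)
  n_broken <- 0
  for (i in 1:100) {
    pi_i <- random_composition()
    kappa <- exp(rnorm(1))
    eps_r <- rnorm(6, 0, 0.4)
    # reversible path: eps_n = 0
    Qr <- nr_rate_matrix(pi_i, kappa, eps_r)
    st <- stationary_distribution(Qr)
    flow <- st * Qr
    expect_lt(max(abs(flow - t(flow))), 1e-12)
    # non-reversible path
    eps_n <- rnorm(12, 0, 0.4)
    Qn <- nr_rate_matrix(pi_i, kappa, eps_r, eps_n)
    stn <- stationary_distribution(Qn)
    flown <- stn * Qn
    if (max(abs(flown - t(flown))) > 1e-6) n_broken <- n_broken + 1
  }
  expect_gte(n_broken, 99)  # generically non-reversible

  # literal-formula oracle for a fixed draw, before normalization
  pi_f <- c(0.15, 0.25, 0.35, 0.25)
  kappa <- 1.7
  eps_r <- seq(-0.3, 0.2, length.out = 6)
  eps_n <- seq(0.25, -0.3, length.out = 12)
  nuc <- c("A", "C", "G", "T")
  p6 <- c("AC", "AG", "AT", "CG", "CT", "GT")
  p12 <- c("AC", "AG", "AT", "CA", "CG", "CT",
           "GA", "GC", "GT", "TA", "TC", "TG")
  raw <- matrix(0, 4, 4, dimnames = list(nuc, nuc))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    trans <- paste0(nuc[i], nuc[j]) %in% c("AG", "GA", "CT", "TC")
    raw[i, j] <- pi_f[j] * (if (trans) kappa else 1) *
      exp(eps_r[match(paste0(sort(c(nuc[i], nuc[j])), collapse = ""), p6)]) *
      exp(eps_n[match(paste0(nuc[i], nuc[j]), p12)])
  }
  Q <- nr_rate_matrix(pi_f, kappa, eps_r, eps_n)
  off <- row(Q) != col(Q)
  # normalization preserves off-diagonal ratios
  expect_equal(Q[off] / Q[2, 1], raw[off] / raw[2, 1], tolerance = 1e-12)
})

test_that("stationary_distribution matches an independent null-space solve", {
  set.seed(6)
  for (i in 1:20) {
    Q <- nr_rate_matrix(random_composition(), exp(rnorm(1)),
                        rnorm(6, 0, 0.5), rnorm(12, 0, 0.5))
    v <- stationary_distribution(Q)
    ns <- MASS::Null(Q)  # null space of t(t(Q)) = left null space of Q
    expect_equal(ncol(ns), 1L)
    ref <- as.numeric(ns / sum(ns))
    expect_equal(unname(v), ref, tolerance = 1e-10)
    expect_lt(max(abs(v %*% Q)), 1e-10)
  }
})

test_that("transition probabilities: identity at t=0, JC closed form,
           uniform limit, Chapman-Kolmogorov", {
  jc <- hky_rate_matrix(rep(0.25, 4), 1)
  expect_equal(transition_probabilities(jc, 0), diag(4))
  for (t in c(0.01, 0.1, 0.5, 1, 3)) {
    P <- transition_probabilities(jc, t)
    expect_equal(unname(diag(P)), rep(0.25 + 0.75 * exp(-4 * t / 3), 4),
                 tolerance = 1e-10)
    expect_equal(rowSums(P), setNames(rep(1, 4), c("A", "C", "G", "T")),
                 tolerance = 1e-12)
  }
  expect_equal(unname(transition_probabilities(jc, 500)),
               matrix(0.25, 4, 4), tolerance = 1e-9)
  set.seed(7)
  for (i in 1:20) {
    Q <- nr_rate_matrix(random_composition(), exp(rnorm(1)),
                        rnorm(6, 0, 0.5), rnorm(12, 0, 0.5))
    s <- runif(1, 0, 5); t <- runif(1, 0, 5)
    lhs <- transition_probabilities(Q, s) %*% transition_probabilities(Q, t)
    expect_equal(lhs, transition_probabilities(Q, s + t), tolerance = 1e-9)
  }
})

test_that("discrete gamma rates: single category, concentration limit,
           exact alpha=1 K=2 values, mean exactly one", {
  expect_equal(discrete_gamma_rates(2, 1), 1)
  expect_equal(discrete_gamma_rates(1e6, 4), rep(1, 4), tolerance = 1e-3)
  # alpha=1, K=2: conditional means of Exp(1) below/above its median
  expect_equal(discrete_gamma_rates(1, 2),
               c(1 - log(2), 1 + log(2)), tolerance = 1e-6)
  set.seed(8)
  for (i in 1:10) {
    r <- discrete_gamma_rates(exp(rnorm(1)), sample(2:8, 1))
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(r >= 0), info = "rates non-negative")
    expect_false(is.unsorted(r))
  }
})

test_that("gc_content adds the G and C frequencies and is monotone", {
  expect_equal(gc_content(rep(0.25, 4)), 0.5)
  expect_equal(gc_content(c(0.1, 0.4, 0.3, 0.2)), 0.7)
  g1 <- gc_content(c(0.3, 0.2, 0.2, 0.3))
  g2 <- gc_content(c(0.2, 0.2, 0.3, 0.3))  # pi_G up at pi_A's expense
  expect_gt(g2, g1)
})

test_that("HB branch matrices: counts, root sharing, homogeneous collapse", {
  set.seed(9)
  for (n in c(3, 5)) {
    tree <- random_rooted_tree(n)
    keys <- phyloroot:::hb_branch_keys(phyloroot:::rt_from_phylo(tree))
    expect_length(keys, 2 * n - 4)
    params <- random_hb_params(tree)
    bm <- hb_branch_matrices(params, tree)
    expect_length(bm$Q, 2 * n - 2)
    root_node <- n + 1L
    for (i in seq_len(nrow(tree$edge))) {
      if (tree$edge[i, 1] == root_node)
        expect_equal(bm$pi_edge[[i]], params$pi_root)
      st <- stationary_distribution(bm$Q[[i]])
      expect_equal(unname(st), unname(bm$pi_edge[[i]]), tolerance = 1e-10)
    }
  }
  # all compositions equal -> one shared GTR matrix everywhere
  tree <- random_rooted_tree(5)
  eq <- random_hb_params(tree, equal = TRUE)
  bm <- hb_branch_matrices(eq, tree)
  for (i in seq_along(bm$Q)) expect_equal(bm$Q[[i]], bm$Q[[1]],
                                          tolerance = 1e-12)
})
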