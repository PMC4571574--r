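# Shared fixture builders: random trees, parameters and alignments are
# generated in code under fixed seeds.

random_composition <- function() {
  p <- rgamma(4, 2) + 0.05
  composition_vector(p / sum(p))
}

random_nr_params <- function(K = 1, nonrev = TRUE, alpha = 1) {
  nr_parameters(pi = random_composition(),
                kappa = exp(rnorm(1, 0, 0.5)),
                eps_r = rnorm(6, 0, 0.3),
                eps_n = if (nonrev) rnorm(12, 0, 0.3) else rep(0, 12),
                sigma_r = 0.3, sigma_n = if (nonrev) 0.3 else 0,
                alpha = alpha, K = K)
}

random_hb_params <- function(tree, K = 1, equal = FALSE, alpha = 1) {
  keys <- phyloroot:::hb_branch_keys(phyloroot:::rt_from_phylo(tree))
  pi_root <- random_composition()
  pib <- setNames(lapply(keys, function(k)
    if (equal) pi_root else random_composition()), keys)
  hb_parameters(tree, rho = rexp(6) + 0.2, pi_root = pi_root,
                pi_branch = pib, s = 0.5, alpha = alpha, K = K)
}

random_alignment <- function(labels, n_sites = 20) {
  nt_alignment(setNames(vapply(labels, function(l)
    paste(sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
          collapse = ""), ""), labels))
}

# The GC-shifted 6-taxon HB configuration used for root-recovery work: one
# root-side subtree at GC 0.3, the other at GC 0.7, a compositionally
# distinctive root, rRNA-like transition-rich exchangeabilities, and short
# pendant branches (so no tip reaches its branch equilibrium, which would
# make pendant rootings near-perfect mimics of the truth).
gc_shift_setup <- function() {
  tree <- read_rooted_tree(paste0("(((A:0.15,B:0.15):0.4,C:0.5):0.5,",
                                  "((D:0.15,E:0.15):0.4,F:0.5):0.5);"))
  keys <- phyloroot:::hb_branch_keys(phyloroot:::rt_from_phylo(tree))
  gcpi <- function(g) c(0.64 * (1 - g), 0.36 * g, 0.64 * g, 0.36 * (1 - g))
  side1 <- c("A", "B", "C")
  pib <- setNames(lapply(keys, function(k) {
    labs <- strsplit(k, ",", fixed = TRUE)[[1]]
    if (all(labs %in% side1)) gcpi(0.3) else gcpi(0.7)
  }), keys)
  params <- hb_parameters(tree, rho = c(1, 4, 1, 1, 4, 1),
                          pi_root = c(0.18, 0.32, 0.18, 0.32),
                          pi_branch = pib, s = 0.5, alpha = 1, K = 1)
  list(tree = tree, params = params, true_split = root_split(tree)$key)
}

empty_alignment <- function(labels) {
  nt_alignment(matrix(character(0), nrow = length(labels), ncol = 0,
                      dimnames = list(labels, NULL)))
}
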