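# File I/O: FASTA / relaxed PHYLIP alignments, trace tables, YAML run
# configuration.

#' Read a nucleotide alignment
#'
#' FASTA or relaxed sequential PHYLIP (parsed with [ape::read.dna()]).
#' Case-insensitive; `U` is mapped to `T`; gaps and IUPAC ambiguity codes
#' are kept and later marginalized by the likelihood.
#'
#' @param path Readable file path.
#' @param format `"fasta"` (default) or `"phylip"`.
#' @return An [nt_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  mat <- tryCatch(
    ape::read.dna(path, format = if (format == "fasta") "fasta"
                                 else "sequential",
                  as.character = TRUE, as.matrix = TRUE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(dim(mat)))
    stop("ragged alignment in '", path, "': sequences differ in length")
  nt_alignment(toupper(mat))
}

#' Write an alignment as FASTA
#'
#' @param aln An [nt_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "nt_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$labels)) {
    writeLines(paste0(">", aln$labels[i]), con)
    writeLines(paste(aln$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Write the scalar trace of an MCMC fit as TSV
#'
#' One row per retained sample: iteration, log-likelihood, log-prior, the
#' model's scalar parameters and the canonical root-split string.  A
#' companion newick file with one rooted tree per sample can be written too.
#'
#' @param fit A `root_mcmc` fit.
#' @param path Output TSV path.
#' @param trees_path Optional path for the sampled trees (newick, one per
#'   line).
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path, trees_path = NULL) {
  stopifnot(inherits(fit, "root_mcmc"))
  utils::write.table(fit$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(trees_path)) {
    nwk <- vapply(fit$samples,
                  function(s) write_rooted_tree(rt_to_phylo(s$tree)), "")
    writeLines(nwk, trees_path)
  }
  invisible(path)
}

#' Read a trace TSV written by [write_trace()]
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_trace <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read a YAML run configuration
#'
#' Recognized keys: `model` ("NR"/"HB"), `alignment`, `format`, `tree`,
#' `seed`, `K`, `n_iter`, `burnin`, `thin`, `out_dir`, and a `priors` block
#' whose entries override [prior_spec()] fields.  Unknown keys are rejected,
#' so typos fail loudly rather than silently running defaults.
#'
#' @param path YAML file path.
#' @return List with `model`, `alignment`, `format`, `tree`, `seed`, `K`,
#'   `options` ([mcmc_options()]), `prior` ([prior_spec()]), `out_dir`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("model", "alignment", "format", "tree", "seed", "K",
             "n_iter", "burnin", "thin", "out_dir", "priors")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model) || !cfg$model %in% c("NR", "HB"))
    stop("config must set model: NR or HB")
  prior <- do.call(prior_spec, as.list(cfg$priors %||% list()))
  opts <- mcmc_options(n_iter = cfg$n_iter %||% 10000,
                       burnin = cfg$burnin %||% 0.25,
                       thin = cfg$thin %||% 10)
  list(model = cfg$model, alignment = cfg$alignment,
       format = cfg$format %||% "fasta", tree = cfg$tree,
       seed = cfg$seed %||% 1L, K = cfg$K %||% 4L,
       options = opts, prior = prior, out_dir = cfg$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' A machine-readable JSON record (seed, model, options, package version,
#' acceptance rates) sufficient to re-run the job, written alongside the
#' outputs.
#'
#' @param fit A `root_mcmc` fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path) {
  stopifnot(inherits(fit, "root_mcmc"))
  m <- list(package = "phyloroot",
            version = as.character(utils::packageVersion("phyloroot")),
            model = fit$model, seed = fit$seed, K = fit$K,
            n_iter = fit$options$n_iter, burnin = fit$options$burnin,
            thin = fit$options$thin,
            n_taxa = length(fit$labels), n_sites = fit$n_sites,
            acceptance = stats::setNames(as.list(fit$acceptance$rate),
                                         fit$acceptance$move))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a root-split posterior table as TSV
#'
#' @param rsp A [root_split_posterior()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_root_splits <- function(rsp, path) {
  utils::write.table(as.data.frame(rsp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a consensus tree as newick or NEXUS
#'
#' NEXUS output wraps the newick (with supports as internal node labels) in
#' a minimal `trees` block.
#'
#' @param cons A [majority_rule_consensus()] tree.
#' @param path Output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(cons, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  phy <- cons
  class(phy) <- "phylo"
  if (format == "newick") {
    writeLines(ape::write.tree(phy, digits = 10), path)
  } else {
    writeLines(c("#NEXUS", "begin trees;",
                 paste0("  tree consensus = [&R] ",
                        ape::write.tree(phy, digits = 10)),
                 "end;"), path)
  }
  invisible(path)
}
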