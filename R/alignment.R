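# Nucleotide alignment container and IUPAC handling.

IUPAC_STATES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"))

# 4 x nsymbol indicator matrix, columns named by symbol
iupac_indicator_matrix <- function() {
  sym <- names(IUPAC_STATES)
  m <- matrix(0, 4, length(sym), dimnames = list(NUC, sym))
  for (s in sym) m[IUPAC_STATES[[s]], s] <- 1
  m
}

#' Construct a nucleotide alignment
#'
#' @param sequences Named character vector of equal-length sequences
#'   (A/C/G/T, IUPAC ambiguity codes, `-` gaps; `U` is mapped to `T`, case
#'   ignored), or a character matrix (taxa x sites) with rownames.
#' @return Object of class `nt_alignment`: list with `labels`, `seq` (taxa x
#'   sites character matrix) and `n_sites`.
#' @examples
#' aln <- nt_alignment(c(t1 = "ACGT", t2 = "ACGA"))
#' @export
nt_alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    labels <- rownames(sequences)
    mat <- sequences
  } else {
    labels <- names(sequences)
    if (is.null(labels)) stop("sequences must be named by taxon")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L)
      stop("ragged alignment: sequence '",
           labels[which.min(lens)], "' has length ", min(lens),
           " but others have ", max(lens))
    mat <- do.call(rbind, strsplit(sequences, ""))
    rownames(mat) <- labels
  }
  if (is.null(labels) || anyDuplicated(labels))
    stop("taxon labels must be present and unique")
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- !(mat %in% names(IUPAC_STATES))
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1L]
    rc <- arrayInd(idx, dim(mat))
    stop("illegal character '", mat[idx], "' in sequence '",
         labels[rc[1L]], "' at site ", rc[2L])
  }
  structure(list(labels = labels, seq = mat, n_sites = ncol(mat)),
            class = "nt_alignment")
}

#' @export
print.nt_alignment <- function(x, ...) {
  cat("Nucleotide alignment:", length(x$labels), "taxa,",
      x$n_sites, "sites\n")
  invisible(x)
}

#' Compress an alignment into site patterns
#'
#' Identical columns are collapsed into unique patterns with weights; the
#' likelihood of an alignment is the weight-sum of per-pattern
#' log-likelihoods.  Weights always sum to the site count.
#'
#' @param aln An [nt_alignment()].
#' @return List with `patterns` (taxa x n_pattern character matrix) and
#'   `weights` (integer vector).
#' @export
compress_patterns <- function(aln) {
  stopifnot(inherits(aln, "nt_alignment"))
  if (aln$n_sites == 0L)
    return(list(patterns = aln$seq, weights = integer(0)))
  key <- apply(aln$seq, 2L, paste, collapse = "")
  tab <- table(factor(key, levels = unique(key)))
  list(patterns = aln$seq[, match(names(tab), key), drop = FALSE],
       weights = as.integer(tab))
}

# 4 x nPat x nTaxa cube of tip indicators, taxa ordered as `order_labels`.
tip_partials <- function(patterns, labels, order_labels) {
  ind <- iupac_indicator_matrix()
  n_pat <- ncol(patterns)
  out <- array(0, dim = c(4L, max(n_pat, 1L), length(order_labels)))
  idx <- match(order_labels, labels)
  if (anyNA(idx)) stop("alignment taxa do not match tree leaves")
  for (t in seq_along(order_labels)) {
    if (n_pat > 0L)
      out[, , t] <- ind[, patterns[idx[t], ], drop = FALSE]
  }
  out
}
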