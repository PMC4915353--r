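#' Sample alignment with known ancestral sequence
#'
#' The unit passed to all downstream statistics: n equal-length nucleotide
#' sequences plus the true ancestral sequence, held sparsely as a set of
#' variant columns against the ancestral background. At construction, columns
#' where every sampled sequence carries the ancestral allele are dropped;
#' columns fixed for a derived allele are retained (they matter for
#' segregating-site bookkeeping).
#'
#' @param geno integer matrix (n x P, alleles 1..4): sampled alleles at the
#'   variant columns.
#' @param positions 1-based sites of the variant columns.
#' @param ancestral integer vector (length L, alleles 1..4): the true
#'   ancestral sequence.
#' @param labels sequence identifiers (default `seq_1..seq_n`).
#' @return A `sample_alignment`.
#' @export
sample_alignment <- function(geno, positions, ancestral, labels = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  stopifnot(n >= 1, ncol(geno) == length(positions),
            all(geno %in% 1:4), all(ancestral %in% 1:4),
            all(positions >= 1), all(positions <= length(ancestral)),
            !anyDuplicated(positions))
  if (is.null(labels)) labels <- paste0("seq_", seq_len(n))
  stopifnot(length(labels) == n)
  ord <- order(positions)
  geno <- geno[, ord, drop = FALSE]
  positions <- positions[ord]
  anc <- as.integer(ancestral[positions])
  keep <- colSums(geno != matrix(anc, n, length(anc), byrow = TRUE)) > 0
  structure(list(
    n = n, L = length(ancestral),
    geno = geno[, keep, drop = FALSE],
    positions = as.integer(positions[keep]),
    anc = anc[keep],
    ancestral = as.integer(ancestral),
    labels = as.character(labels)
  ), class = "sample_alignment")
}

#' @export
print.sample_alignment <- function(x, ...) {
  cat(sprintf("<sample_alignment> n = %d, L = %d, %d variant column(s)\n",
              x$n, x$L, length(x$positions)))
  invisible(x)
}

#' Draw a sample from a population
#'
#' `n` individuals uniformly without replacement; the sample carries the true
#' ancestral states of the population's polymorphic sites.
#'
#' @param pop a `wf_population`.
#' @param n sample size.
#' @param idx optional explicit individual indices (overrides random draw).
#' @return A `sample_alignment`.
#' @export
draw_sample <- function(pop, n, idx = NULL) {
  if (is.null(idx)) {
    if (n > pop$N) stop("sample size n (", n, ") exceeds population size N (", pop$N, ")")
    idx <- sample.int(pop$N, n)
  }
  anc_seq <- pop$background
  anc_seq[pop$positions] <- pop$anc
  sample_alignment(pop$geno[idx, , drop = FALSE], pop$positions, anc_seq,
                   labels = paste0("ind_", idx))
}

# Materialise the full n x L character matrix (lowercase nucleotides).
alignment_matrix <- function(x, include_ancestral = FALSE) {
  base <- NUC[x$ancestral]
  rows <- lapply(seq_len(x$n), function(i) {
    v <- base
    v[x$positions] <- NUC[x$geno[i, ]]
    v
  })
  m <- do.call(rbind, rows)
  rownames(m) <- x$labels
  if (include_ancestral) {
    m <- rbind(m, base)
    rownames(m)[nrow(m)] <- ANCESTRAL_LABEL
  }
  m
}

ANCESTRAL_LABEL <- "__ANCESTRAL__"

#' Write or read a sample alignment as FASTA
#'
#' Standard FASTA with one extra record holding the ancestral sequence under
#' the reserved label `__ANCESTRAL__`. The write/read pair round-trips
#' sequences and labels losslessly.
#'
#' @param sample a `sample_alignment`.
#' @param path file path.
#' @return `write_sample` returns `path` invisibly; `read_sample` returns a
#'   `sample_alignment`.
#' @export
write_sample <- function(sample, path) {
  stopifnot(inherits(sample, "sample_alignment"))
  if (sample$n < 1) stop("empty alignment")
  m <- alignment_matrix(sample, include_ancestral = TRUE)
  ape::write.FASTA(ape::as.DNAbin(m), path)
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- tolower(as.character(as.matrix(dna)))
  ai <- match(ANCESTRAL_LABEL, rownames(m))
  if (is.na(ai))
    stop("FASTA file lacks the ancestral record '", ANCESTRAL_LABEL, "'")
  anc <- match(m[ai, ], NUC)
  seqs <- m[-ai, , drop = FALSE]
  if (any(is.na(anc)) || any(is.na(match(seqs, NUC))))
    stop("alignment contains non-ACGT characters")
  gen <- matrix(match(seqs, NUC), nrow = nrow(seqs))
  diff_cols <- which(colSums(gen != matrix(anc, nrow(gen), length(anc), byrow = TRUE)) > 0)
  sample_alignment(gen[, diff_cols, drop = FALSE], diff_cols, anc,
                   labels = rownames(seqs))
}
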