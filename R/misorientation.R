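#' Simulate an outgroup sequence under the misorientation model
#'
#' At every variant column of the sample, the outgroup nucleotide equals the
#' true ancestral nucleotide with probability `q_true`; otherwise it is drawn
#' uniformly among the other three nucleotides (JC69). Non-variant sites copy
#' the ancestral sequence. Used as a fixture to exercise the q estimators and
#' the SFS correction.
#'
#' @param sample a `sample_alignment`.
#' @param q_true probability in (0.5, 1] that the outgroup matches the
#'   ancestral state.
#' @return integer vector (length L, alleles 1..4): the outgroup sequence.
#' @export
simulate_outgroup <- function(sample, q_true) {
  stopifnot(q_true > 0.5, q_true <= 1)
  out <- sample$ancestral
  for (cc in seq_along(sample$positions)) {
    j <- sample$positions[cc]
    if (runif(1) > q_true) {
      others <- setdiff(1:4, sample$ancestral[j])
      out[j] <- others[sample.int(3, 1)]
    }
  }
  out
}

#' Polarise an SFS by an outgroup sequence
#'
#' Re-derives the unfolded SFS using the outgroup nucleotide as the putative
#' ancestral state (the situation faced with real data, where misorientation
#' occurs whenever outgroup and true ancestor disagree). Sites where the
#' outgroup differs from both alleles of a biallelic SNP cannot be polarised;
#' their proportion among segregating sites is the quantity x used to
#' estimate q.
#'
#' @param sample a `sample_alignment`.
#' @param outgroup integer vector (length L, alleles 1..4).
#' @return list with `sfs` (the observed, outgroup-polarised
#'   `site_frequency_spectrum`), `x` (proportion of segregating sites whose
#'   outgroup nucleotide differs from both SNP alleles), and `n_unpolarized`.
#' @export
outgroup_polarized_sfs <- function(sample, outgroup) {
  stopifnot(length(outgroup) == sample$L)
  n <- sample$n
  xi <- numeric(n - 1)
  n_seg <- 0L; n_unpol <- 0L
  for (cc in seq_along(sample$positions)) {
    alle <- sample$geno[, cc]
    uniq <- unique(alle)
    if (length(uniq) != 2) next # monomorphic or multiallelic in sample
    n_seg <- n_seg + 1L
    og <- outgroup[sample$positions[cc]]
    if (!og %in% uniq) { n_unpol <- n_unpol + 1L; next }
    i <- sum(alle != og) # derived = allele differing from putative ancestor
    xi[i] <- xi[i] + 1
  }
  list(sfs = sfs_from_counts(xi, n),
       x = if (n_seg > 0) n_unpol / n_seg else NA_real_,
       n_unpolarized = n_unpol, n_segregating = n_seg)
}

#' Estimate the outgroup-ancestor agreement probability q
#'
#' q is the probability that the outgroup nucleotide equals the true
#' ancestral nucleotide. It is estimated from x, the proportion of
#' segregating sites whose outgroup nucleotide differs from both SNP alleles.
#' Mode `"jc_consistent"` (default) inverts P(U|S) = 2(1-q)/3, the JC69
#' probability that a misoriented outgroup lands on neither SNP allele,
#' giving q = 1 - 3x/2. Mode `"paper_literal"` returns x/2, the printed rule,
#' kept for comparability although it cannot yield q near 1 for small x.
#'
#' @param x proportion in \[0, 1\].
#' @param mode `"jc_consistent"` or `"paper_literal"`.
#' @return estimate of q.
#' @export
estimate_q <- function(x, mode = c("jc_consistent", "paper_literal")) {
  mode <- match.arg(mode)
  stopifnot(x >= 0, x <= 1)
  if (mode == "paper_literal") return(x / 2)
  q <- 1 - 3 * x / 2
  if (q < 0) warning("x > 2/3 gives a negative q under the JC-consistent estimator")
  q
}

#' Correct an observed SFS for ancestral misorientation
#'
#' Under the mixing model xi_k_obs = q xi_k + (1-q) xi_{n-k}, a site
#' misoriented with probability 1-q has its frequency class reflected. Mode
#' `"exact_inverse"` (default) solves the 2x2 system exactly:
#' xi_k = (q xi_k_obs - (1-q) xi_{n-k}_obs) / (2q - 1). Mode
#' `"paper_literal"` applies the printed variant
#' xi_k = (xi_k_obs - (1-q) xi_{n-k}_obs) / (2q - 1), which omits the factor
#' q on the first term. Negative corrected counts are clamped to 0 with a
#' warning.
#'
#' @param sfs_obs a `site_frequency_spectrum` (observed, outgroup-polarised).
#' @param q agreement probability, must exceed 0.5.
#' @param mode `"exact_inverse"` or `"paper_literal"`.
#' @return the corrected `site_frequency_spectrum`.
#' @export
correct_sfs <- function(sfs_obs, q, mode = c("exact_inverse", "paper_literal")) {
  mode <- match.arg(mode)
  if (q <= 0.5) stop("q must exceed 0.5 for the mixing model to be invertible")
  n <- sfs_obs$n
  obs <- sfs_obs$xi
  refl <- rev(obs) # xi_{n-k}
  xi <- if (mode == "exact_inverse") (q * obs - (1 - q) * refl) / (2 * q - 1)
        else (obs - (1 - q) * refl) / (2 * q - 1)
  if (any(xi < -1e-9)) warning("negative corrected SFS counts clamped to 0")
  xi <- pmax(xi, 0)
  sfs_from_counts(xi, n)
}

#' Forward misorientation mixing of an SFS
#'
#' Applies the expectation of the mixing model,
#' xi_k_obs = q xi_k + (1-q) xi_{n-k}; the exact-inverse correction undoes it
#' algebraically.
#'
#' @param sfs a `site_frequency_spectrum` (true spectrum).
#' @param q agreement probability.
#' @return the mixed (expected observed) `site_frequency_spectrum`.
#' @export
mix_sfs <- function(sfs, q) {
  stopifnot(q >= 0, q <= 1)
  sfs_from_counts(q * sfs$xi + (1 - q) * rev(sfs$xi), sfs$n)
}
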