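#' Unfolded site frequency spectrum
#'
#' Counts, for i = 1..n-1, the polymorphic sites at which exactly i of the n
#' sampled sequences carry the derived allele, polarised by the alignment's
#' known ancestral sequence. Sites with more than two alleles (counting the
#' ancestral allele) are excluded, as are sites fixed for a derived allele in
#' the sample; both exclusions are reported in attributes.
#'
#' @param sample a `sample_alignment`.
#' @return object of class `site_frequency_spectrum`: list with `n`, `xi`
#'   (length n-1), `S` (sum of `xi`), and counts `n_multiallelic`,
#'   `n_fixed_derived` of excluded sites.
#' @export
unfolded_sfs <- function(sample) {
  stopifnot(inherits(sample, "sample_alignment"))
  n <- sample$n
  xi <- integer(n - 1)
  n_multi <- 0L; n_fixed <- 0L
  for (cc in seq_along(sample$positions)) {
    alle <- sample$geno[, cc]
    anc <- sample$anc[cc]
    uniq <- unique(alle)
    n_alleles <- length(union(uniq, anc))
    if (n_alleles > 2) { n_multi <- n_multi + 1L; next }
    i <- sum(alle != anc)
    if (i == 0) next
    if (i == n) { n_fixed <- n_fixed + 1L; next }
    xi[i] <- xi[i] + 1L
  }
  structure(list(n = n, xi = xi, S = sum(xi),
                 n_multiallelic = n_multi, n_fixed_derived = n_fixed,
                 folded = FALSE),
            class = "site_frequency_spectrum")
}

#' Construct an SFS from counts
#'
#' @param xi nonnegative counts xi_1..xi_{n-1}.
#' @param n sample size; default `length(xi) + 1`.
#' @return a `site_frequency_spectrum`.
#' @export
sfs_from_counts <- function(xi, n = length(xi) + 1) {
  stopifnot(all(xi >= 0), length(xi) == n - 1)
  structure(list(n = n, xi = as.numeric(xi), S = sum(xi),
                 n_multiallelic = 0L, n_fixed_derived = 0L, folded = FALSE),
            class = "site_frequency_spectrum")
}

#' @export
print.site_frequency_spectrum <- function(x, ...) {
  cat(sprintf("<site_frequency_spectrum> n = %d, S = %g (%d multiallelic, %d fixed-derived excluded)\n",
              x$n, x$S, x$n_multiallelic, x$n_fixed_derived))
  invisible(x)
}

#' Transformed (normalized) SFS
#'
#' The vector i * xi_i, i = 1..n-1, normalized by its sum. Because
#' E\[xi_i\] = theta/i under the standard neutral model, each term is an
#' unbiased estimator of theta and the transformed spectrum has a flat
#' expectation 1/(n-1); departures from flatness are the visual signature of
#' selection, sampling bias or misorientation.
#'
#' @param sfs a `site_frequency_spectrum`.
#' @return numeric vector of length n-1 summing to 1.
#' @export
transform_normalize <- function(sfs) {
  i <- seq_len(sfs$n - 1)
  w <- i * sfs$xi
  tot <- sum(w)
  if (tot <= 0) stop("SFS has no segregating sites; transformed SFS undefined")
  w / tot
}

#' Segregating sites and segregating fraction
#'
#' `segregating_sites` counts sample-polymorphic biallelic sites (the S that
#' enters the SFS and Tajima's D); `segregating_fraction` divides by the
#' locus length.
#'
#' @param sample a `sample_alignment`.
#' @return integer count, or fraction in \[0, 1\].
#' @export
segregating_sites <- function(sample) {
  unfolded_sfs(sample)$S
}

#' @rdname segregating_sites
#' @export
segregating_fraction <- function(sample) {
  segregating_sites(sample) / sample$L
}

#' Watterson expectation for the number of segregating sites
#'
#' Under the standard neutral model, E\[S\] = theta * L * a_n with
#' a_n = sum_{i=1}^{n-1} 1/i.
#'
#' @param theta per-site population-scaled mutation rate.
#' @param L locus length.
#' @param n sample size (>= 2).
#' @return expected count of segregating sites.
#' @export
watterson_expected_S <- function(theta, L, n) {
  stopifnot(n >= 2)
  theta * L * sum(1 / seq_len(n - 1))
}

#' Tajima's D
#'
#' The normalized difference between the pairwise-diversity and
#' segregating-sites estimators of theta (Tajima 1989). Computed over the
#' sample's biallelic segregating sites; undefined (NA) when S = 0, and such
#' replicates are excluded from scenario averages.
#'
#' @param sample a `sample_alignment`, or a `site_frequency_spectrum`.
#' @return numeric; `NA` if there are no segregating sites.
#' @export
tajimas_d <- function(sample) {
  sfs <- if (inherits(sample, "site_frequency_spectrum")) sample
         else unfolded_sfs(sample)
  n <- sfs$n
  S <- sfs$S
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  # mean pairwise differences from the unfolded spectrum
  pih <- sum(2 * i * (n - i) * sfs$xi) / (n * (n - 1))
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pih - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
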