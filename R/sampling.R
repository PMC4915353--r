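#' Biased sampling schemes over a clustered population
#'
#' The three sampling biases are drawn from a PAM clustering of the full
#' final population: `sample_uniform` takes one individual per cluster
#' (requires k = 100 clusters for a sample of 100); `sample_clustered` takes
#' all 100 from a single cluster (k = 10); `sample_mixed` takes 91 from one
#' focal cluster and one from each of the remaining nine (k = 10). Cluster
#' choices among eligible clusters are uniform.
#'
#' @param pop a `wf_population` (the full final population).
#' @param clustering a `pam_clustering` of that population.
#' @param size total sample size (default 100).
#' @return A `sample_alignment`; the drawn indices are in attribute `idx`.
#' @export
sample_uniform <- function(pop, clustering, size = clustering$k) {
  if (clustering$k != size)
    stop("uniform sampling of ", size, " individuals needs k = ", size, " clusters")
  idx <- vapply(seq_len(clustering$k), function(cl) {
    members <- which(clustering$assignment == cl)
    if (length(members) == 0) stop("cluster ", cl, " is empty")
    members[sample.int(length(members), 1)]
  }, integer(1))
  out <- draw_sample(pop, length(idx), idx = idx)
  attr(out, "idx") <- idx
  out
}

#' @rdname sample_uniform
#' @export
sample_clustered <- function(pop, clustering, size = 100) {
  sizes <- tabulate(clustering$assignment, clustering$k)
  eligible <- which(sizes >= size)
  if (length(eligible) == 0)
    stop("no cluster has >= ", size, " members (largest has ", max(sizes),
         "); re-cluster or re-simulate")
  cl <- eligible[sample.int(length(eligible), 1)]
  members <- which(clustering$assignment == cl)
  idx <- members[sample.int(length(members), size)]
  out <- draw_sample(pop, length(idx), idx = idx)
  attr(out, "idx") <- idx
  attr(out, "cluster") <- cl
  out
}

#' @rdname sample_uniform
#' @param n_focal individuals drawn from the focal cluster (default 91).
#' @export
sample_mixed <- function(pop, clustering, size = 100, n_focal = 91) {
  k <- clustering$k
  if (size != n_focal + (k - 1))
    stop("mixed sampling needs size = n_focal + k - 1 (", n_focal + k - 1, ")")
  sizes <- tabulate(clustering$assignment, k)
  eligible <- which(sizes >= n_focal)
  if (length(eligible) == 0)
    stop("no cluster has >= ", n_focal, " members for the focal draw")
  focal <- eligible[sample.int(length(eligible), 1)]
  members <- which(clustering$assignment == focal)
  idx <- members[sample.int(length(members), n_focal)]
  for (cl in setdiff(seq_len(k), focal)) {
    others <- which(clustering$assignment == cl)
    if (length(others) == 0) stop("cluster ", cl, " is empty")
    idx <- c(idx, others[sample.int(length(others), 1)])
  }
  out <- draw_sample(pop, length(idx), idx = idx)
  attr(out, "idx") <- idx
  attr(out, "focal_cluster") <- focal
  out
}
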