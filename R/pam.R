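#' Partitioning around medoids (PAM)
#'
#' k-medoids clustering of a distance matrix: the BUILD heuristic seeds k
#' medoids greedily, then SWAP repeatedly performs the single
#' (medoid, non-medoid) exchange that most lowers the total distance of every
#' point to its nearest medoid, until no exchange improves the cost — a local
#' optimum. Ties in assignment go to the lowest-index medoid; the procedure
#' is deterministic for a given matrix.
#'
#' @param dm a `dist_matrix`.
#' @param k number of clusters, 2 <= k <= number of individuals (k = 1 and
#'   k = n are permitted degenerate cases).
#' @return object of class `pam_clustering`: list with `k`, `medoids`
#'   (indices), `assignment` (cluster id per individual, 1..k), `cost`
#'   (sum of within-cluster distances to medoids) and `cost_trace` (cost
#'   after BUILD and after each swap; non-increasing).
#' @export
pam_cluster <- function(dm, k) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- length(dm$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  res <- pam_core(dm$d, as.integer(k))
  # res$assignment holds the rank of the nearest medoid among sorted medoids
  structure(list(k = as.integer(k),
                 medoids = as.integer(res$medoids),
                 assignment = as.integer(res$assignment),
                 cost = res$cost,
                 cost_trace = res$cost_trace,
                 labels = dm$labels),
            class = "pam_clustering")
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat(sprintf("<pam_clustering> k = %d, cost = %.6g, sizes: %s\n",
              x$k, x$cost, paste(tabulate(x$assignment, x$k), collapse = " ")))
  invisible(x)
}

#' Recompute a clustering's cost from scratch
#'
#' @param clustering a `pam_clustering`.
#' @param dm the `dist_matrix` it was built from.
#' @return total within-cluster distance to medoids.
#' @export
clustering_cost <- function(clustering, dm) {
  sum(dm$d[cbind(seq_along(clustering$assignment),
                 clustering$medoids[clustering$assignment])])
}

#' Write a clustering as a two-column TSV (individual, cluster)
#'
#' @param clustering a `pam_clustering`.
#' @param path file path.
#' @export
write_clustering <- function(clustering, path) {
  utils::write.table(
    data.frame(individual = clustering$labels, cluster = clustering$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
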