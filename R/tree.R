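#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; each merge places the new node at half the
#' between-cluster average distance, so the tree is ultrametric by
#' construction, with branch lengths in the units of the input distances
#' (substitutions/site).
#'
#' @param dm a `dist_matrix`.
#' @return an ultrametric, binary `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (any(dm$d < 0)) stop("negative distances")
  if (length(dm$labels) < 2) stop("need at least 2 taxa")
  d <- dm$d
  dimnames(d) <- list(dm$labels, dm$labels)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  # as.phylo.hclust halves merge heights, giving root-to-tip = height/2
  stats::reorder(tr)
}

#' Node depth of every tip (for ultrametricity checks)
#' @noRd
tip_depths <- function(tree) {
  nh <- ape::node.depth.edgelength(tree)
  nh[seq_len(ape::Ntip(tree))]
}

#' Coalescent intervals of an ultrametric binary tree
#'
#' Sorted internal-node heights (measured from the tips, 0 = present) cut the
#' tree into intervals; during the interval ending at the i-th coalescence
#' (from the present) there are n - i + 1 lineages. Returns intervals from
#' k = n down to k = 2.
#'
#' @param tree an ultrametric binary `phylo`.
#' @param tol ultrametricity tolerance on root-to-tip depths.
#' @return object of class `coalescent_intervals_cb`: data.frame with columns
#'   `k` (lineage count) and `duration`; attribute `depth` is the tree depth.
#' @export
coalescent_intervals <- function(tree, tol = 1e-8) {
  n <- ape::Ntip(tree)
  # rooted binary: exactly n - 1 internal nodes (is.binary alone accepts
  # unrooted basal trifurcations)
  if (tree$Nnode != n - 1) stop("tree must be binary and rooted")
  depths <- tip_depths(tree)
  depth <- max(depths)
  if (diff(range(depths)) > tol * max(depth, 1))
    stop("tree is not ultrametric")
  heights <- sort(unname(ape::branching.times(tree)))
  stopifnot(length(heights) == n - 1)
  bounds <- c(0, heights)
  out <- data.frame(k = seq(n, 2), duration = diff(bounds))
  class(out) <- c("coalescent_intervals_cb", "data.frame")
  attr(out, "depth") <- heights[n - 1]
  out
}

#' Simulate a constant-size Kingman coalescent tree
#'
#' While k lineages remain, the waiting time to the next coalescence is
#' Exponential with rate C(k,2)/`scaled_size`, and a uniformly random pair
#' merges. With time in substitutions/site, `scaled_size` is the product
#' Ne * u that skyline estimators target. Serves as the independent oracle
#' for skyline parameter recovery.
#'
#' @param n number of tips.
#' @param scaled_size coalescent time scale (Ne * u).
#' @return an ultrametric binary `phylo`.
#' @export
simulate_kingman_tree <- function(n, scaled_size) {
  stopifnot(n >= 2, scaled_size > 0)
  n_nodes <- 2L * n - 1L
  edge <- matrix(0L, n_nodes - 1L, 2)
  edge_len <- numeric(n_nodes - 1L)
  height <- numeric(n_nodes)            # node heights, tips at 0
  active <- seq_len(n)                  # node ids of live lineages
  t_now <- 0
  next_node <- 2L * n - 1L              # internal ids n+1..2n-1; root = n+1
  ei <- 1L
  for (k in seq(n, 2)) {
    t_now <- t_now + rexp(1, rate = choose(k, 2) / scaled_size)
    pair <- sample.int(k, 2)
    parent <- next_node
    next_node <- next_node - 1L
    height[parent] <- t_now
    for (ch in active[pair]) {
      edge[ei, ] <- c(parent, ch)
      edge_len[ei] <- t_now - height[ch]
      ei <- ei + 1L
    }
    active <- c(active[-pair], parent)
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L), class = "phylo")
  # internal ids were assigned root-last; relabel so the root is n+1
  tr <- ape::read.tree(text = ape::write.tree(tr))
  tr
}

#' Newick I/O with skyline-suitability validation
#'
#' Thin wrappers over standard Newick reading/writing that enforce the
#' preconditions of the skyline computations on read: binary topology and
#' branch lengths present.
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @param require_binary reject multifurcating trees (default TRUE).
#' @return `read_newick` returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path, require_binary = TRUE) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick file: ", path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (require_binary && tr$Nnode != ape::Ntip(tr) - 1)
    stop("tree is not binary and rooted; skyline computations need bifurcating trees")
  tr
}
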