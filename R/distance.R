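#' Pairwise sequence distances
#'
#' p-distances (proportion of differing sites) or JC69-corrected distances
#' d = -(3/4) log(1 - 4p/3) between all pairs of sequences. Works on a
#' `sample_alignment` or a `wf_population` (where individuals share the
#' monomorphic background, so only polymorphic columns contribute).
#'
#' @param x a `sample_alignment` or `wf_population`.
#' @param correction `"p"` (raw) or `"JC69"`.
#' @return a `dist_matrix`: list with `labels` and symmetric matrix `d`
#'   (substitutions/site, zero diagonal).
#' @export
distance_matrix <- function(x, correction = c("p", "JC69")) {
  correction <- match.arg(correction)
  if (inherits(x, "wf_population")) {
    geno <- x$geno; L <- x$L
    labels <- paste0("ind_", seq_len(x$N))
  } else if (inherits(x, "sample_alignment")) {
    geno <- x$geno; L <- x$L; labels <- x$labels
  } else stop("x must be a wf_population or sample_alignment")
  if (nrow(geno) < 2) stop("need at least 2 sequences")
  p <- hamming_counts(geno) / L
  d <- if (correction == "JC69") jc69_distance(p) else p
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d), class = "dist_matrix")
}

jc69_distance <- function(p) {
  if (any(p >= 0.75)) stop("p-distance >= 3/4: JC69 correction undefined")
  -0.75 * log1p(-4 * p / 3)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d sequences, mean off-diagonal distance %.4g\n",
              length(x$labels), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Write or read a distance matrix in square PHYLIP format
#'
#' @param dm a `dist_matrix`.
#' @param path file path.
#' @return `read_phylip_dist` returns a `dist_matrix`.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$labels)), con)
  for (i in seq_along(dm$labels)) {
    writeLines(paste(c(dm$labels[i], sprintf("%.10g", dm$d[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[[:space:]]+")
  labels <- vapply(parts, `[`, "", 1)
  d <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d), class = "dist_matrix")
}
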