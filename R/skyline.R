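#' Classic skyline plot
#'
#' For each coalescent interval with k lineages and duration t_k, the moment
#' estimator of the (scaled) population size is M_k = t_k * k(k-1)/2: the
#' interval duration times the number of lineage pairs. With branch lengths
#' in substitutions/site the estimates are in units of Ne * u. Zero-duration
#' intervals give zero estimates and are flagged.
#'
#' @param intervals a `coalescent_intervals_cb`.
#' @return object of class `skyline_estimate`: data.frame with columns
#'   `t_start`, `t_end` (0 = present, increasing into the past), `Ne_u`,
#'   `segment`; attributes `epsilon`, `K` (segment count), `logLik`, `AIC`,
#'   `n_zero` (zero estimates).
#' @export
classic_skyline <- function(intervals) {
  generalized_skyline(intervals, epsilon = 0)
}

#' Generalized skyline plot
#'
#' Small intervals are pooled (from the present backwards) until each
#' composite's total duration reaches `epsilon`; a terminal composite shorter
#' than `epsilon` is merged into its predecessor. A composite spanning c
#' coalescences with sub-intervals (k_i, t_i) takes the maximum-likelihood
#' estimate N = (1/c) * sum C(k_i, 2) t_i, constant across the composite.
#' `epsilon = 0` reproduces the classic skyline.
#'
#' @param intervals a `coalescent_intervals_cb`.
#' @param epsilon pooling threshold, in the tree's time units (>= 0).
#' @return a `skyline_estimate`; see [classic_skyline()].
#' @export
generalized_skyline <- function(intervals, epsilon) {
  stopifnot(epsilon >= 0)
  k <- intervals$k
  tt <- intervals$duration
  m <- length(k)
  seg <- integer(m)
  cur <- 1L
  acc <- 0
  for (i in seq_len(m)) {
    seg[i] <- cur
    acc <- acc + tt[i]
    if (acc >= epsilon && i < m) { cur <- cur + 1L; acc <- 0 }
  }
  # merge a trailing too-short composite into its predecessor
  if (max(seg) > 1) {
    last <- seg == max(seg)
    if (sum(tt[last]) < epsilon) seg[last] <- max(seg) - 1L
  }
  seg <- match(seg, unique(seg))
  K <- max(seg)
  pairs <- choose(k, 2)
  est <- vapply(seq_len(K), function(s) {
    sub <- seg == s
    sum(pairs[sub] * tt[sub]) / sum(sub)
  }, numeric(1))
  # per-interval log-likelihood under the piecewise-constant coalescent
  Nhat <- est[seg]
  ll <- if (any(Nhat <= 0)) -Inf else sum(log(pairs / Nhat) - pairs * tt / Nhat)
  bounds <- cumsum(c(0, tt))
  out <- data.frame(t_start = bounds[-(m + 1)], t_end = bounds[-1],
                    Ne_u = Nhat, segment = seg, k = k)
  class(out) <- c("skyline_estimate", "data.frame")
  attr(out, "epsilon") <- epsilon
  attr(out, "K") <- K
  attr(out, "logLik") <- ll
  attr(out, "AIC") <- 2 * K - 2 * ll
  attr(out, "n_zero") <- sum(est == 0)
  out
}

#' AIC selection of the pooling parameter epsilon
#'
#' Computes the generalized skyline for every epsilon in the grid and
#' returns the one minimizing AIC = 2K - 2 logLik (K = number of composite
#' segments); ties go to the smaller epsilon. The default grid is 0 plus 20
#' logarithmically spaced values from depth/1000 to the tree depth.
#'
#' @param intervals a `coalescent_intervals_cb`.
#' @param epsilon_grid nonempty vector of candidate epsilons.
#' @return list with `epsilon`, `skyline` (the selected `skyline_estimate`)
#'   and `aic_table` (data.frame epsilon/K/AIC).
#' @export
aic_select_epsilon <- function(intervals, epsilon_grid = NULL) {
  if (is.null(epsilon_grid)) {
    depth <- sum(intervals$duration)
    if (depth <= 0)
      stop("tree depth is zero (all sequences identical); no skyline is defined")
    epsilon_grid <- c(0, exp(seq(log(depth / 1e3), log(depth), length.out = 20)))
  }
  stopifnot(length(epsilon_grid) >= 1)
  epsilon_grid <- sort(epsilon_grid)
  fits <- lapply(epsilon_grid, function(e) generalized_skyline(intervals, e))
  aics <- vapply(fits, attr, numeric(1), "AIC")
  if (all(!is.finite(aics)))
    stop("all candidate skylines are degenerate (zero estimates)")
  best <- which.min(aics) # which.min takes the first (smallest epsilon) on ties
  list(epsilon = epsilon_grid[best], skyline = fits[[best]],
       aic_table = data.frame(epsilon = epsilon_grid,
                              K = vapply(fits, attr, numeric(1), "K"),
                              AIC = aics))
}

#' Skyline amplitude
#'
#' The ratio between the maximal and minimal Ne * u values across segments —
#' the summary used to compare demographic distortion across scenarios
#' (1 = perfectly constant inferred size).
#'
#' @param est a `skyline_estimate`.
#' @return max/min ratio (>= 1).
#' @export
skyline_amplitude <- function(est) {
  v <- vapply(split(est$Ne_u, est$segment), `[`, numeric(1), 1)
  if (min(v) <= 0) stop("skyline contains zero estimates; amplitude undefined (pool with epsilon > 0)")
  max(v) / min(v)
}

#' Write a skyline estimate as TSV
#'
#' @param est a `skyline_estimate`.
#' @param path file path.
#' @export
write_skyline <- function(est, path) {
  df <- data.frame(t_start = est$t_start, t_end = est$t_end, Ne_u = est$Ne_u,
                   segment_index = est$segment, epsilon = attr(est, "epsilon"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
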