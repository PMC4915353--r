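#' Run a replicate batch for one scenario
#'
#' For each replicate: simulate the population, draw the sample according to
#' the sampling scheme (`"random"` takes the simulator's uniform sample;
#' the biased schemes cluster the full final population with PAM first),
#' then compute the segregating-site statistics, the unfolded and
#' transformed SFS, and — optionally — the UPGMA genealogy with its
#' AIC-selected generalized skyline and amplitude. Replicate r runs under a
#' seed derived deterministically from `cfg$seed`, so any replicate is
#' reproducible in isolation and reruns are byte-identical.
#'
#' @param cfg a `scenario_config`.
#' @param scheme `"random"`, `"uniform"`, `"clustered"` or `"mixed"`.
#' @param replicates number of replicates (default `cfg$replicate_count`).
#' @param skyline compute UPGMA + generalized skyline per replicate
#'   (default TRUE; the dominant cost after the simulation itself).
#' @param out_dir if non-NULL, per-replicate FASTA/Newick/TSV outputs and a
#'   JSON provenance block are written under `out_dir/<scenario>/<rep>/`.
#' @param keep_samples retain each replicate's `sample_alignment` (and the
#'   biased-scheme extras) in the result (default FALSE to save memory).
#' @return object of class `scenario_result`: list with `scenario`, `cfg`,
#'   `scheme`, `stats` (per-replicate data.frame: replicate, seed, S,
#'   S_frac, tajima_D, amplitude, epsilon, K), `sfs` (matrix replicates x
#'   (n-1) of xi counts), and `samples` (if kept).
#' @export
run_scenario <- function(cfg, scheme = c("random", "uniform", "clustered", "mixed"),
                         replicates = cfg$replicate_count, skyline = TRUE,
                         out_dir = NULL, keep_samples = FALSE) {
  scheme <- match.arg(scheme)
  seeds <- replicate_seeds(cfg$seed, replicates)
  n1 <- cfg$n_sample - 1
  stats_list <- vector("list", replicates)
  sfs_mat <- matrix(NA_real_, replicates, n1)
  samples <- if (keep_samples) vector("list", replicates) else NULL

  for (r in seq_len(replicates)) {
    set.seed(seeds[r])
    sim <- run_simulation(cfg)
    smp <- switch(scheme,
      random = sim$sample,
      uniform = sample_uniform(sim$population,
                               pam_cluster(distance_matrix(sim$population),
                                           cfg$n_sample),
                               size = cfg$n_sample),
      clustered = sample_clustered(sim$population,
                                   pam_cluster(distance_matrix(sim$population), 10),
                                   size = cfg$n_sample),
      mixed = sample_mixed(sim$population,
                           pam_cluster(distance_matrix(sim$population), 10),
                           size = cfg$n_sample,
                           n_focal = cfg$n_sample - 9)
    )
    sfs <- unfolded_sfs(smp)
    sfs_mat[r, ] <- sfs$xi
    amp <- eps <- K <- NA_real_
    tr <- NULL
    if (skyline && sfs$S > 0) {
      tr <- upgma_tree(distance_matrix(smp, correction = "JC69"))
      sel <- aic_select_epsilon(coalescent_intervals(tr))
      amp <- tryCatch(skyline_amplitude(sel$skyline), error = function(e) NA_real_)
      eps <- sel$epsilon
      K <- attr(sel$skyline, "K")
    }
    stats_list[[r]] <- data.frame(
      replicate = r, seed = seeds[r], S = sfs$S, S_frac = sfs$S / cfg$L,
      n_multiallelic = sfs$n_multiallelic, tajima_D = tajimas_d(sfs),
      amplitude = amp, epsilon = eps, K = K)
    if (keep_samples) samples[[r]] <- smp
    if (!is.null(out_dir)) {
      rep_dir <- file.path(out_dir, cfg$name, sprintf("rep_%03d", r))
      dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
      write_sample(smp, file.path(rep_dir, "sample.fasta"))
      if (!is.null(tr)) {
        write_newick(tr, file.path(rep_dir, "upgma.nwk"))
        write_skyline(sel$skyline, file.path(rep_dir, "skyline.tsv"))
      }
      utils::write.table(
        data.frame(i = seq_len(n1), xi = sfs$xi,
                   transformed = if (sfs$S > 0) transform_normalize(sfs) else NA),
        file.path(rep_dir, "sfs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  stats <- do.call(rbind, stats_list)
  res <- structure(list(scenario = cfg$name, cfg = cfg, scheme = scheme,
                        stats = stats, sfs = sfs_mat, samples = samples),
                   class = "scenario_result")
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, cfg$name), recursive = TRUE, showWarnings = FALSE)
    utils::write.table(stats, file.path(out_dir, cfg$name, "replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- list(config = unclass(cfg), scheme = scheme, replicates = replicates,
                 seeds = seeds,
                 package_version = as.character(utils::packageVersion("coalbias")))
    jsonlite::write_json(prov, file.path(out_dir, cfg$name, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%s sampling), %d replicate(s)\n",
              x$scenario, x$scheme, nrow(x$stats)))
  cat(sprintf("  mean S = %.1f (S/L = %.4g), mean Tajima's D = %.3f\n",
              mean(x$stats$S), mean(x$stats$S_frac),
              mean(x$stats$tajima_D, na.rm = TRUE)))
  invisible(x)
}

#' Long-format comparison table across scenarios
#'
#' One row per scenario x statistic with mean, SD, SE, median and quartiles;
#' the amplitude ratio is included when skylines were computed. SD/SE are NA
#' (flagged) for single-replicate scenarios.
#'
#' @param results list of `scenario_result` objects.
#' @return data.frame with columns scenario, scheme, statistic, n, mean, sd,
#'   se, median, q1, q3.
#' @export
summarize_scenarios <- function(results) {
  stopifnot(length(results) >= 1)
  if (inherits(results, "scenario_result")) results <- list(results)
  rows <- lapply(results, function(res) {
    stats <- res$stats
    do.call(rbind, lapply(c("S", "S_frac", "tajima_D", "amplitude"), function(st) {
      v <- stats[[st]]
      v <- v[is.finite(v)]
      n <- length(v)
      data.frame(scenario = res$scenario, scheme = res$scheme, statistic = st,
                 n = n,
                 mean = if (n) mean(v) else NA_real_,
                 sd = if (n > 1) stats::sd(v) else NA_real_,
                 se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
                 median = if (n) stats::median(v) else NA_real_,
                 q1 = if (n) unname(stats::quantile(v, 0.25)) else NA_real_,
                 q3 = if (n) unname(stats::quantile(v, 0.75)) else NA_real_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
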