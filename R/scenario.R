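#' Scenario configuration
#'
#' Bundles every parameter of one simulation experiment: population size,
#' locus, mutation, the three-point-mass selection model, gene conversion,
#' sampling and replication. `theta` is the per-site population-scaled
#' mutation rate, theta = 2 N u, so the per-site per-generation mutation
#' probability is `theta / (2 N)`.
#'
#' @param N haploid population size.
#' @param L locus length in nucleotides.
#' @param theta per-site population-scaled mutation rate (2 N u).
#' @param n_sample number of individuals drawn at the end of a run.
#' @param class_probs length-3 probabilities that a new mutation is
#'   deleterious, neutral or adaptive (in that order); must sum to 1.
#' @param s_del,s_adv per-generation selection coefficients attached to
#'   deleterious (< 0) and adaptive (> 0) mutations.
#' @param conv_init_ratio gene-conversion initiation rate over the mutation
#'   rate, per site (rho/mu); 0 disables conversion.
#' @param tract_mean mean conversion tract length in nucleotides
#'   (geometric distribution).
#' @param burnin_gens generations evolved from the monomorphic start;
#'   default 10 N.
#' @param seed master seed for the experiment.
#' @param replicate_count number of replicates a scenario run performs.
#' @param name optional scenario label.
#' @return An object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config(N = 100, L = 1000, theta = 0.01, n_sample = 20)
#' cfg$u_site
#' @export
scenario_config <- function(N = 1000L, L = 20000L, theta = 0.02,
                            n_sample = 100L,
                            class_probs = c(0, 1, 0),
                            s_del = 0, s_adv = 0,
                            conv_init_ratio = 0, tract_mean = 542,
                            burnin_gens = NULL, seed = 1L,
                            replicate_count = 10L, name = "custom") {
  if (is.null(burnin_gens)) burnin_gens <- 10L * as.integer(N)
  cfg <- structure(list(
    N = as.integer(N), L = as.integer(L), theta = theta,
    n_sample = as.integer(n_sample),
    class_probs = as.numeric(class_probs),
    s_del = s_del, s_adv = s_adv,
    conv_init_ratio = conv_init_ratio, tract_mean = tract_mean,
    burnin_gens = as.integer(burnin_gens), seed = as.integer(seed),
    replicate_count = as.integer(replicate_count), name = name
  ), class = "scenario_config")
  cfg$u_site <- cfg$theta / (2 * cfg$N)
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$N >= 2, cfg$L >= 1, cfg$theta >= 0)
  if (cfg$n_sample > cfg$N)
    stop("n_sample (", cfg$n_sample, ") exceeds population size N (", cfg$N, ")")
  p <- cfg$class_probs
  if (length(p) != 3 || any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
    stop("class_probs must be 3 probabilities (deleterious, neutral, adaptive) summing to 1")
  if (cfg$u_site >= 1) stop("theta/(2N) must be < 1")
  if (cfg$tract_mean < 1) stop("tract_mean must be >= 1")
  if (cfg$conv_init_ratio < 0) stop("conv_init_ratio must be >= 0")
  if (cfg$s_del > 0) stop("s_del must be <= 0")
  if (cfg$s_adv < 0) stop("s_adv must be >= 0")
  if (cfg$s_del <= -1) stop("s_del must be > -1 (fitness must stay positive)")
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> ", x$name, "\n", sep = "")
  cat(sprintf("  N = %d, L = %d, theta = %g (u = %g), n = %d\n",
              x$N, x$L, x$theta, x$u_site, x$n_sample))
  cat(sprintf("  classes (del, neu, adv) = (%.4g, %.4g, %.4g); s_del = %g, s_adv = %g\n",
              x$class_probs[1], x$class_probs[2], x$class_probs[3], x$s_del, x$s_adv))
  cat(sprintf("  conversion: rho/mu = %g, mean tract = %g nt\n",
              x$conv_init_ratio, x$tract_mean))
  cat(sprintf("  burn-in = %d generations, %d replicate(s), seed = %d\n",
              x$burnin_gens, x$replicate_count, x$seed))
  invisible(x)
}

# Mutation-class probabilities from E. coli genomic rates: the deleterious and
# adaptive genomic rates divided by the total genomic mutation rate
# u_per_gen * genome_size; the remainder is neutral.
ecoli_class_probs <- function(genomic_del = 2e-4, genomic_adv = 1e-5,
                              u_per_gen = 8.9e-11, genome_size = 5e6) {
  total <- u_per_gen * genome_size
  p_del <- genomic_del / total
  p_adv <- genomic_adv / total
  c(p_del, 1 - p_del - p_adv, p_adv)
}

#' Named scenario presets
#'
#' Ready-made configurations for the study's scenario families. The
#' selection presets use the E. coli mutation-class probabilities derived
#' from genomic rates (about 45% deleterious, 2.2% adaptive). "weak_selection"
#' sets N|s| = 5; "ecoli_strong" represents the strong-selection regime
#' (2N|s| >> 1) with per-generation coefficients capped at |s| = 0.5, since a
#' literal rescaling of E. coli's Ne·s to a simulated N of 1000 would exceed
#' 1. The recombination presets set the conversion initiation rate to 1x and
#' 10x the mutation rate with a mean tract of 542 nt.
#'
#' @param name one of `"neutral"`, `"weak_selection"`, `"ecoli_strong"`,
#'   `"recomb_1x"`, `"recomb_10x"`.
#' @param ... overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name, ...) {
  presets <- list(
    neutral        = list(),
    weak_selection = list(class_probs = ecoli_class_probs(),
                          s_del = -5 / 1000, s_adv = 5 / 1000),
    ecoli_strong   = list(class_probs = ecoli_class_probs(),
                          s_del = -0.5, s_adv = 0.5),
    recomb_1x      = list(conv_init_ratio = 1, tract_mean = 542),
    recomb_10x     = list(conv_init_ratio = 10, tract_mean = 542)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[name]], list(...))
  args$name <- name
  do.call(scenario_config, args)
}

#' Read or write a scenario configuration file
#'
#' Configurations round-trip through YAML or JSON (chosen by file
#' extension).
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg a `scenario_config`.
#' @return `read_scenario_config` returns a `scenario_config`;
#'   `write_scenario_config` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lst$u_site <- NULL
  do.call(scenario_config, lst)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$u_site <- NULL
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path, precision = 15)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Deterministic per-replicate seeds derived from the master seed.
replicate_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
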