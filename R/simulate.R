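#' Run a forward Wright-Fisher simulation
#'
#' Evolves a monomorphic constant-size haploid population for
#' `cfg$burnin_gens` generations under finite-sites JC69 mutation, the
#' three-point-mass selection model and (optionally) gene conversion, using
#' the compiled engine, then draws `cfg$n_sample` individuals uniformly
#' without replacement. Each generation applies mutation, then gene
#' conversion, then multinomial fitness-weighted reproduction. All
#' randomness comes from R's global RNG; call `set.seed()` (or pass
#' `seed`) for reproducibility.
#'
#' @param cfg a `scenario_config`.
#' @param seed optional seed applied before the run; default uses the
#'   current RNG state.
#' @return list with elements `population` (a `wf_population`) and `sample`
#'   (a `sample_alignment`).
#' @examples
#' cfg <- scenario_config(N = 50, L = 500, theta = 0.02, n_sample = 10,
#'                        burnin_gens = 200)
#' res <- run_simulation(cfg, seed = 1)
#' res$sample
#' @export
run_simulation <- function(cfg, seed = NULL) {
  validate_scenario_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  raw <- wf_engine_run(cfg$N, cfg$L, cfg$u_site, cfg$burnin_gens,
                       cfg$class_probs[1], cfg$class_probs[3],
                       cfg$s_del, cfg$s_adv,
                       cfg$conv_init_ratio, cfg$tract_mean)
  pop <- structure(list(
    N = cfg$N, L = cfg$L,
    background = raw$background,
    positions = raw$positions,
    geno = raw$geno,
    anc = raw$anc,
    s = raw$s,
    logfit = raw$logfit,
    generation = raw$generations
  ), class = "wf_population")
  smp <- draw_sample(pop, cfg$n_sample)
  list(population = pop, sample = smp)
}
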