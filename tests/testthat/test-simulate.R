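small_neutral <- function(seed) {
  cfg <- scenario_config(N = 300, L = 1500, theta = 0.02, n_sample = 20,
                         burnin_gens = 3000)
  run_simulation(cfg, seed = seed)
}

test_that("runs are reproducible from the seed", {
  a <- run_simulation(scenario_config(N = 50, L = 400, theta = 0.05,
                                      n_sample = 10, burnin_gens = 300), seed = 99)
  b <- run_simulation(scenario_config(N = 50, L = 400, theta = 0.05,
                                      n_sample = 10, burnin_gens = 300), seed = 99)
  expect_identical(a$sample$geno, b$sample$geno)
  expect_identical(a$population$background, b$population$background)
})

test_that("no mutation means no segregating sites", {
  res <- run_simulation(scenario_config(N = 50, L = 400, theta = 0,
                                        n_sample = 10, burnin_gens = 100), seed = 1)
  expect_equal(segregating_sites(res$sample), 0)
  expect_length(res$population$positions, 0)
})

test_that("oversampling the population is a parameter error", {
  expect_error(scenario_config(N = 20, n_sample = 30), "exceeds population size")
})

test_that("engine output satisfies the fitness and ancestral-state invariants", {
  cfg <- scenario_config(N = 100, L = 800, theta = 0.04, n_sample = 20,
                         class_probs = c(0.4, 0.55, 0.05),
                         s_del = -0.02, s_adv = 0.02, burnin_gens = 800)
  res <- run_simulation(cfg, seed = 17)
  pop <- res$population
  expect_equal(pop$logfit, population_fitness(pop), tolerance = 1e-8)
  # every derived allele present has a coefficient recorded
  for (cc in seq_along(pop$positions)) {
    present <- unique(pop$geno[, cc])
    expect_false(any(is.na(pop$s[present, cc])))
    expect_equal(pop$s[pop$anc[cc], cc], 0)
  }
  # sample ancestral sequence equals column ancestors at polymorphic sites
  expect_equal(res$sample$ancestral[pop$positions], pop$anc)
})

test_that("the compiled engine and the R generation steps agree on neutral diversity", {
  cfg <- scenario_config(N = 60, L = 500, theta = 0.04, n_sample = 15,
                         burnin_gens = 600)
  s_engine <- vapply(1:8, function(r) {
    segregating_sites(run_simulation(cfg, seed = 1000 + r)$sample)
  }, numeric(1))
  s_rpath <- vapply(1:8, function(r) {
    set.seed(2000 + r)
    pop <- new_population(cfg$N, cfg$L)
    for (g in seq_len(cfg$burnin_gens)) pop <- step_generation(pop, cfg)
    segregating_sites(draw_sample(pop, cfg$n_sample))
  }, numeric(1))
  se <- sqrt(var(s_engine) / 8 + var(s_rpath) / 8)
  expect_lt(abs(mean(s_engine) - mean(s_rpath)), 3 * se + 1e-9)
})

test_that("neutral simulations sit at Watterson mutation-drift equilibrium", {
  sims <- cached("neutral_small", function() lapply(1:15, small_neutral))
  S <- vapply(sims, function(x) segregating_sites(x$sample), numeric(1))
  expected <- watterson_expected_S(0.02, 1500, 20)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("mean Tajima's D is near zero without selection", {
  sims <- cached("neutral_small", function() lapply(1:15, small_neutral))
  D <- vapply(sims, function(x) tajimas_d(x$sample), numeric(1))
  D <- D[!is.na(D)]
  expect_gt(length(D), 10)
  expect_lt(abs(mean(D)), 3 * sd(D) / sqrt(length(D)))
})

test_that("weak selection depresses Tajima's D below the neutral mean", {
  sims <- cached("neutral_small", function() lapply(1:15, small_neutral))
  D_neu <- vapply(sims, function(x) tajimas_d(x$sample), numeric(1))
  cfg <- scenario_config(N = 300, L = 1500, theta = 0.02, n_sample = 20,
                         class_probs = coalbias:::ecoli_class_probs(),
                         s_del = -5 / 300, s_adv = 5 / 300, burnin_gens = 3000)
  D_sel <- vapply(1:12, function(r) tajimas_d(run_simulation(cfg, seed = 500 + r)$sample),
                  numeric(1))
  expect_lt(mean(D_sel, na.rm = TRUE), mean(D_neu, na.rm = TRUE))
})

test_that("gene conversion preserves mean diversity but shrinks SFS variance", {
  sims <- cached("neutral_small", function() lapply(1:15, small_neutral))
  S_neu <- vapply(sims, function(x) segregating_sites(x$sample), numeric(1))
  tr_neu <- t(vapply(sims, function(x) transform_normalize(unfolded_sfs(x$sample)),
                     numeric(19)))
  cfg <- scenario_config(N = 300, L = 1500, theta = 0.02, n_sample = 20,
                         conv_init_ratio = 10, tract_mean = 100, burnin_gens = 3000)
  sims_c <- lapply(1:15, function(r) run_simulation(cfg, seed = 700 + r))
  S_conv <- vapply(sims_c, function(x) segregating_sites(x$sample), numeric(1))
  tr_conv <- t(vapply(sims_c, function(x) transform_normalize(unfolded_sfs(x$sample)),
                      numeric(19)))
  se <- sqrt(var(S_neu) / 15 + var(S_conv) / 15)
  expect_lt(abs(mean(S_neu) - mean(S_conv)), 3 * se)
  # recombination decorrelates genealogies along the locus: per-bin variance drops
  expect_lt(mean(apply(tr_conv, 2, var)), mean(apply(tr_neu, 2, var)))
})
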