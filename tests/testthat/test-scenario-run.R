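tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(N = 120, L = 800, theta = 0.02, n_sample = 20,
         burnin_gens = 1200, replicate_count = 4, name = "tiny"),
    list(...))
  do.call(scenario_config, args)
}

test_that("scenario runs are deterministic and write byte-identical outputs", {
  cfg <- tiny_cfg(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_scenario(cfg, "random", out_dir = d1)
  r2 <- run_scenario(cfg, "random", out_dir = d2)
  expect_identical(r1$stats, r2$stats)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 0)
  for (f in f1) {
    if (grepl("provenance", f)) next # provenance may embed package version only
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("replicate statistics agree with recomputation from written FASTA", {
  cfg <- tiny_cfg(seed = 9, replicate_count = 2)
  d <- withr::local_tempdir()
  res <- run_scenario(cfg, "random", out_dir = d, skyline = FALSE)
  smp <- read_sample(file.path(d, "tiny", "rep_001", "sample.fasta"))
  expect_equal(segregating_sites(smp), res$stats$S[1])
  expect_equal(tajimas_d(smp), res$stats$tajima_D[1], tolerance = 1e-12)
})

test_that("a neutral batch matches the Watterson expectation", {
  cfg <- tiny_cfg(seed = 21, replicate_count = 10)
  res <- cached("tiny_batch", function() run_scenario(cfg, "random", skyline = FALSE))
  expected <- watterson_expected_S(cfg$theta, cfg$L, cfg$n_sample)
  se <- sd(res$stats$S) / sqrt(nrow(res$stats))
  expect_lt(abs(mean(res$stats$S) - expected), 3 * se)
})

test_that("the mixed scheme enforces the focal-plus-singletons composition", {
  cfg <- scenario_config(N = 150, L = 600, theta = 0.03, n_sample = 20,
                         burnin_gens = 1500, name = "mix", seed = 33)
  res <- run_scenario(cfg, "mixed", replicates = 2, skyline = FALSE,
                      keep_samples = TRUE)
  for (smp in res$samples) {
    expect_equal(smp$n, 20)
    expect_length(attr(smp, "idx"), 20)
  }
})

test_that("summaries have one row per scenario and statistic", {
  res <- cached("tiny_batch", function() {
    run_scenario(tiny_cfg(seed = 21, replicate_count = 10), "random", skyline = FALSE)
  })
  tab <- summarize_scenarios(list(res))
  expect_equal(nrow(tab), 4)
  expect_setequal(tab$statistic, c("S", "S_frac", "tajima_D", "amplitude"))
  expect_equal(tab$mean[tab$statistic == "S"], mean(res$stats$S))
  expect_equal(tab$n[tab$statistic == "amplitude"], 0) # skylines disabled

  single <- run_scenario(tiny_cfg(seed = 40, replicate_count = 1), "random",
                         skyline = FALSE)
  tab1 <- summarize_scenarios(list(single))
  expect_true(all(is.na(tab1$sd[tab1$statistic == "S"])))
})

test_that("neutral scenario summary centres Tajima's D on zero", {
  res <- cached("tiny_batch", function() {
    run_scenario(tiny_cfg(seed = 21, replicate_count = 10), "random", skyline = FALSE)
  })
  tab <- summarize_scenarios(list(res))
  drow <- tab[tab$statistic == "tajima_D", ]
  expect_lt(abs(drow$mean), 3 * drow$se)
})
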