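#!/usr/bin/env Rscript
# Biased sampling from structured samples of an unstructured population.
#
# The full final population is clustered around medoids (PAM) on pairwise
# sequence distances; three schemes then draw the sample: one individual per
# cluster (uniform, k = n), all from one cluster (clustered, k = 10), or a
# focal cluster plus singletons (mixed, k = 10). None of these change the
# population -- only the draw -- yet they reshape the genealogy, the SFS and
# Tajima's D exactly like demographic events would.
#
# Desk scale: N = 500, n = 50 (mixed draws 41 + 9 singletons). Smaller
# populations leave too little contrast between the schemes' genealogies:
# the amplitude comparisons need enough within-cluster coalescent depth to
# separate from a random sample's noise.

library(coalbias)

out_dir <- "results/03_sampling_bias"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_preset("neutral", N = 500, L = 4000, n_sample = 50,
                       burnin_gens = 5000, replicate_count = 12, seed = 301)

runs <- lapply(setNames(nm = c("random", "uniform", "clustered", "mixed")),
               function(scheme) run_scenario(cfg, scheme))

tab <- summarize_scenarios(runs)
write.table(tab, file.path(out_dir, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

S_means <- vapply(runs, function(r) mean(r$stats$S), numeric(1))
cat("Mean segregating sites by scheme:\n"); print(round(S_means, 1))
cat(sprintf("\nClustered-sampling reduction: %.1f-fold fewer segregating sites\n",
            S_means["random"] / S_means["clustered"]))
cat(sprintf("Mean Tajima's D, mixed sampling: %+.3f (random: %+.3f)\n",
            mean(runs$mixed$stats$tajima_D, na.rm = TRUE),
            mean(runs$random$stats$tajima_D, na.rm = TRUE)))

amp <- vapply(runs, function(r) median(r$stats$amplitude, na.rm = TRUE), numeric(1))
cat("\nMedian skyline amplitude (max/min Ne*u) by scheme:\n"); print(round(amp, 2))
for (scheme in c("uniform", "clustered")) {
  p <- wilcox.test(runs[[scheme]]$stats$amplitude, runs$random$stats$amplitude,
                   paired = TRUE, alternative = "greater")$p.value
  cat(sprintf("amplitude(%s) > amplitude(random): one-sided Wilcoxon p = %.4g\n",
              scheme, p))
}
cat("\nNote: these contrasts sharpen with population size; the package's\n")
cat("acceptance tests run the same comparisons at the full study scale\n")
cat("(N = 1000, L = 20000, n = 100).\n")
cat("\nTables written under ", out_dir, "\n")
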