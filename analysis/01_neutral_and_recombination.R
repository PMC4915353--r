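#!/usr/bin/env Rscript
# Neutral baseline and the effect of gene conversion.
#
# A constant-size haploid population should sit at Watterson's mutation-drift
# equilibrium: E[S] = theta * L * a_n, Tajima's D = 0, flat transformed SFS.
# Gene conversion must not change any of those means -- it only decorrelates
# genealogies along the locus, shrinking the between-replicate variance of
# the SFS. This script verifies both claims at desk scale and writes the
# summary tables.
#
# Desk scale: N = 300, L = 2000, with the conversion tract scaled to keep
# tract/L near the full-scale ratio (542/20000); the full study scale
# (presets "neutral"/"recomb_1x"/"recomb_10x") runs the same code, just
# longer. Note that conversion from a uniformly chosen donor adds a small
# extra pair-coalescence rate (a lineage can jump onto the other lineage),
# so very high initiation rates shave a few percent off S; at the study's
# 1x rate the effect is within noise.

library(coalbias)

out_dir <- "results/01_neutral_recombination"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

desk <- function(preset, seed) {
  scenario_preset(preset, N = 300, L = 2000, n_sample = 50, tract_mean = 60,
                  burnin_gens = 3000, replicate_count = 25, seed = seed)
}

runs <- list(
  neutral   = run_scenario(desk("neutral", 101), "random", skyline = FALSE),
  recomb_1x = run_scenario(desk("recomb_1x", 102), "random", skyline = FALSE),
  recomb_10x = run_scenario(desk("recomb_10x", 103), "random", skyline = FALSE)
)

tab <- summarize_scenarios(runs)
write.table(tab, file.path(out_dir, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

expected_S <- watterson_expected_S(0.02, 2000, 50)
cat(sprintf("Watterson expectation for S: %.1f\n", expected_S))
for (nm in names(runs)) {
  st <- runs[[nm]]$stats
  cat(sprintf("%-10s mean S = %6.1f (SE %5.1f)   mean D = %+.3f\n",
              nm, mean(st$S), sd(st$S) / sqrt(nrow(st)),
              mean(st$tajima_D, na.rm = TRUE)))
}

# between-replicate variance of the transformed SFS, bin-averaged: the
# variance-damping signature of recombination
bin_var <- vapply(runs, function(res) {
  tr <- t(apply(res$sfs, 1, function(xi) {
    transform_normalize(sfs_from_counts(xi, res$cfg$n_sample))
  }))
  mean(apply(tr, 2, var))
}, numeric(1))
cat("\nMean per-bin variance of the transformed SFS (should fall with conversion):\n")
print(round(bin_var, 6))
write.table(data.frame(scenario = names(bin_var), mean_bin_variance = bin_var),
            file.path(out_dir, "sfs_bin_variance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nTables written under ", out_dir, "\n")
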