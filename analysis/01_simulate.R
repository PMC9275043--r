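#!/usr/bin/env Rscript
# Stage 1: simulate the default synthetic seascape study and write the
# on-disk fixture every later stage reads: a coastal water mask, nine
# sampling sites along an environmental gradient, 200 individuals genotyped
# at 2000 neutral + 50 adaptive SNPs (plus two planted duplicate pairs),
# and the truth table that makes downstream recovery checkable.

suppressMessages(library(seagea))

seed <- 42L
sim <- simulate_study(sim_config(seed = seed))
dir.create("results", showWarnings = FALSE)
write_fixture(sim, "results/fixture")

cat(sprintf("simulated %d individuals x %d loci over %d sites (seed %d)\n",
            nrow(sim$genotypes$dosage), ncol(sim$genotypes$dosage),
            nrow(sim$sites), seed))
cat(sprintf("planted %d adaptive loci (effect %.1f log-odds/SD), %d duplicate pairs\n",
            sum(sim$truth$is_adaptive), sim$config$effect_size,
            nrow(sim$planted_pairs)))
cat("fixture written to results/fixture/\n")
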