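#!/usr/bin/env Rscript
# Stage 4: environmental variable reduction. Standardize the candidate
# variables, prune collinearity (pairwise |r| > 0.7, then VIF >= 3), and
# forward-select the survivors against the genotype response conditioned
# on the selected spatial eigenvectors.

suppressMessages(library(seagea))

fix <- load_fixture("results/fixture")
Gq <- load_genotypes("results/qc/genotypes_qc.vcf")
samples <- fix$samples[match(Gq$sample_ids, fix$samples$sample_id), ]
mems <- read.csv("results/spatial/mems_selected.csv")
Z <- as.matrix(mems[match(Gq$sample_ids, mems$sample_id), -1, drop = FALSE])

E <- standardize_env(fix$env[match(samples$site, fix$env$site),
                             setdiff(names(fix$env), "site")])
kept <- collinearity_prune(E, r_max = 0.7, vif_max = 3)
cat("after collinearity pruning:", paste(kept, collapse = ", "), "\n")
drops <- attr(kept, "drops")
if (nrow(drops) > 0) print(drops)

Y <- impute_dosage(Gq)
fs <- forward_select_env(Y, E[, kept, drop = FALSE], Z = Z,
                         alpha = 0.05, n_perm = 1000, seed = 42)
cat("retained variables:", paste(fs$retained, collapse = ", "), "\n")
print(fs$steps)

dir.create("results/env", showWarnings = FALSE)
write.csv(data.frame(sample_id = Gq$sample_ids,
                     E[, fs$retained, drop = FALSE]),
          "results/env/env_retained.csv", row.names = FALSE, quote = FALSE)
write.csv(fs$steps, "results/env/env_selection_steps.csv",
          row.names = FALSE, quote = FALSE)
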