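#!/usr/bin/env Rscript
# Stage 5: the genotype-environment association itself. Partial RDA of the
# imputed genotype matrix on the retained environmental variables,
# conditioned on the selected MEMs; permutation ANOVA (overall, per
# variable, per axis, 1000 permutations); +/-3SD outlier detection on the
# significant axes; Spearman assignment of each candidate's best
# environmental predictor; recovery scored against the planted truth.

suppressMessages(library(seagea))

fix <- load_fixture("results/fixture")
Gq <- load_genotypes("results/qc/genotypes_qc.vcf")
mems <- read.csv("results/spatial/mems_selected.csv")
envr <- read.csv("results/env/env_retained.csv")
Z <- as.matrix(mems[match(Gq$sample_ids, mems$sample_id), -1, drop = FALSE])
X <- as.matrix(envr[match(Gq$sample_ids, envr$sample_id), -1, drop = FALSE])

Y <- impute_dosage(Gq)
model <- partial_rda(Y, X, Z)
print(model)

overall <- permutation_significance(model, "overall", n_perm = 1000, seed = 42)
terms <- permutation_significance(model, "term", n_perm = 1000, seed = 42)
axes <- permutation_significance(model, "axis", n_perm = 1000, seed = 42)
cat(sprintf("overall model: F = %.2f, p = %.4g\n",
            overall$statistic, overall$p))
print(terms); print(axes)

sig <- which(axes$p <= 0.05)
cand <- detect_candidates(model, sig, sd_mult = 3)
cand <- assign_predictors(cand, Gq, X)
cat(sprintf("%d candidate loci on axes {%s}\n",
            nrow(cand), paste(sig, collapse = ",")))
print(table(cand$best_predictor))

planted <- fix$truth$locus_id[fix$truth$is_adaptive == "TRUE" |
                                fix$truth$is_adaptive == TRUE]
cat(sprintf("recovery: %.0f%% of planted loci flagged; %.0f%% of flags neutral\n",
            100 * mean(planted %in% cand$locus_id),
            100 * mean(!(cand$locus_id %in% planted))))

dir.create("results/gea", showWarnings = FALSE)
write.csv(cand, "results/gea/candidates.csv", row.names = FALSE, quote = FALSE)
write.csv(rbind(overall, terms, axes), "results/gea/anova.csv",
          row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(partition = as.list(model$partition),
                          eigenvalues = model$eigenvalues),
                     "results/gea/model_summary.json",
                     auto_unbox = TRUE, digits = 10)
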