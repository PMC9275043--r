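#!/usr/bin/env Rscript
# Stage 6: putatively adaptive population structure and diversity, on the
# candidate panel. Per-site observed/expected heterozygosity, pairwise
# Weir-Cockerham F_ST (10,000 permutations, B-Y FDR < 10%), PCA, and EM
# mixture clustering with AIC choice of K over 1-9.

suppressMessages(library(seagea))

fix <- load_fixture("results/fixture")
Gq <- load_genotypes("results/qc/genotypes_qc.vcf")
samples <- fix$samples[match(Gq$sample_ids, fix$samples$sample_id), ]
attr(Gq, "site") <- samples$site
cand <- read.csv("results/gea/candidates.csv")
Gc <- seagea:::.subset_gm(Gq, cols = match(cand$locus_id, Gq$locus_ids))

div <- diversity_by_site(Gc)
print(div)

fst <- pairwise_fst(Gc, n_perm = 10000, q = 0.10, seed = 42)
cat(sprintf("pairwise F_ST range: %.3f-%.3f; %d/%d pairs significant (B-Y, FDR<10%%)\n",
            min(fst$theta[upper.tri(fst$theta)]),
            max(fst$theta[upper.tri(fst$theta)]),
            sum(fst$significant[upper.tri(fst$significant)]),
            sum(upper.tri(fst$theta))))

pca <- genotype_pca(impute_dosage(Gc))
cat("PC1-3 variance explained:",
    paste(sprintf("%.1f%%", 100 * pca$var_explained[1:3]), collapse = ", "),
    "\n")

kc <- choose_k(Gc, k_range = 1:9, method = "AIC", seed = 42)
cat("best-supported K (AIC):", kc$best_k, "\n")
best <- em_cluster(Gc, kc$best_k, seed = 42)

dir.create("results/structure", showWarnings = FALSE)
write.csv(div, "results/structure/diversity.csv", row.names = FALSE,
          quote = FALSE)
write.csv(as.data.frame(fst$theta), "results/structure/fst_theta.csv",
          quote = FALSE)
write.csv(as.data.frame(fst$p_adj), "results/structure/fst_p_adj.csv",
          quote = FALSE)
write.csv(kc$table, "results/structure/k_table.csv", row.names = FALSE,
          quote = FALSE)
q <- data.frame(sample_id = Gc$sample_ids, site = attr(Gc, "site"),
                best$membership)
write.csv(q, "results/structure/q_matrix.csv", row.names = FALSE,
          quote = FALSE)
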