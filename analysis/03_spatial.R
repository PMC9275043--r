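#!/usr/bin/env Rscript
# Stage 3: spatial covariates. Least-cost oceanic distances between the
# individual sampling coordinates, distance-based Moran's eigenvector maps,
# and forward selection of the MEMs against the genotype response
# conditioned on the candidate environmental table (so the spatial control
# captures spatial structure not attributable to the measured gradients).

suppressMessages(library(seagea))

fix <- load_fixture("results/fixture")
Gq <- load_genotypes("results/qc/genotypes_qc.vcf")
samples <- fix$samples[match(Gq$sample_ids, fix$samples$sample_id), ]
attr(Gq, "site") <- samples$site

D <- oceanic_distances(samples, fix$mask)
cat(sprintf("oceanic distances: %d points, %.0f-%.0f km\n",
            nrow(D), min(D[upper.tri(D)]), max(D)))

basis <- build_dbmem(D)
cat(sprintf("dbMEM: %d positive eigenvectors, truncation %.1f km\n",
            ncol(basis$vectors), basis$truncation))

E <- standardize_env(fix$env[match(samples$site, fix$env$site),
                             setdiff(names(fix$env), "site")])
Y <- impute_dosage(Gq)
sel <- forward_select_mems(Y, basis$vectors, Z = E, alpha = 0.05,
                           n_perm = 100, seed = 42)
cat("selected MEMs:",
    paste(colnames(basis$vectors)[sel$selected], collapse = ", "), "\n")

dir.create("results/spatial", showWarnings = FALSE)
mems <- data.frame(sample_id = Gq$sample_ids,
                   basis$vectors[, sel$selected, drop = FALSE])
write.csv(mems, "results/spatial/mems_selected.csv",
          row.names = FALSE, quote = FALSE)
write.csv(sel$steps, "results/spatial/mem_selection_steps.csv",
          row.names = FALSE, quote = FALSE)
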