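#!/usr/bin/env Rscript
# Stage 2: genotype quality control. Individuals with excessive
# missingness are dropped, duplicate/close-kin pairs are pruned at
# |R| > 0.5 from standardized allele sharing, and loci are filtered on
# missingness and minor allele count (MAC >= 3, recomputed after the
# individual removals).

suppressMessages(library(seagea))

fix <- load_fixture("results/fixture")
G <- fix$genotypes
cat(sprintf("input: %d individuals x %d loci\n",
            nrow(G$dosage), ncol(G$dosage)))

G <- filter_individuals(G, max_ind_missing = 0.5)
R <- pairwise_relatedness(G)
G <- prune_related(G, R, threshold = 0.5)
cat("relatedness pruning removed:",
    paste(attr(G, "removed"), collapse = ", "), "\n")

G <- filter_loci(G, max_locus_missing = 0.2, min_mac = 3)
cat(sprintf("after QC: %d individuals x %d loci (%d loci removed)\n",
            nrow(G$dosage), ncol(G$dosage), nrow(attr(G, "removed"))))

dir.create("results/qc", showWarnings = FALSE)
write_vcf(G, "results/qc/genotypes_qc.vcf")
write.csv(data.frame(sample_id = G$sample_ids, site = attr(G, "site")),
          "results/qc/samples_qc.csv", row.names = FALSE, quote = FALSE)
write.csv(attr(G, "removed"), "results/qc/removed_loci.csv",
          row.names = FALSE, quote = FALSE)
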