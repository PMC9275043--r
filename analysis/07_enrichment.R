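#!/usr/bin/env Rscript
# Stage 7: functional context and GO enrichment. Classify each candidate
# SNP's genomic context from the gene models (exonic > intronic > promoter
# > intergenic, 2 kb promoter window) and test GO-term over-representation
# of candidates against the full filtered panel (Fisher's exact test, BH
# FDR <= 5%).

suppressMessages(library(seagea))

fix <- load_fixture("results/fixture")
Gq <- load_genotypes("results/qc/genotypes_qc.vcf")
cand <- read.csv("results/gea/candidates.csv")

ctx <- classify_context(Gq$loci[match(cand$locus_id, Gq$locus_ids), ],
                        fix$gff_path, promoter_bp = 2000)
print(table(ctx$context))

tab <- fisher_enrichment(cand$locus_id, Gq$locus_ids, fix$go_map, q = 0.05)
cat(sprintf("%d GO terms tested, %d over-represented at FDR <= 5%%\n",
            nrow(tab), sum(tab$flag)))
print(head(tab[, c("term", "cand_with", "bg_with", "odds_ratio", "p_adj",
                   "flag")]))

dir.create("results/enrichment", showWarnings = FALSE)
write.csv(ctx, "results/enrichment/context.csv", row.names = FALSE,
          quote = FALSE)
write.csv(tab, "results/enrichment/enrichment.csv", row.names = FALSE,
          quote = FALSE)
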