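# Genomic context of candidate SNPs from GFF3 gene models, and Fisher's
# exact Gene-Ontology over-representation of candidates against the full
# filtered locus panel.

#' Classify the genomic context of SNP positions
#'
#' Precedence: a position inside any exon is `exonic`; inside a gene span
#' but not an exon, `intronic`; within `promoter_bp` upstream of a gene's
#' transcription start (strand-aware) and not inside any gene, `promoter`;
#' otherwise `intergenic`. Loci on contigs absent from the GFF are
#' `intergenic` with a warning.
#'
#' @param loci data.frame with locus_id, contig, pos (1-based).
#' @param gff path to a GFF3 file with gene and exon features.
#' @param promoter_bp promoter window upstream of the TSS (default 2000).
#' @return data.frame: locus_id, gene (or ""), context.
#' @export
classify_context <- function(loci, gff, promoter_bp = 2000) {
  feats <- rtracklayer::import(gff)
  genes <- feats[S4Vectors::mcols(feats)$type == "gene"]
  exons <- feats[S4Vectors::mcols(feats)$type == "exon"]
  known <- unique(as.character(GenomicRanges::seqnames(genes)))
  missing_ctg <- setdiff(unique(loci$contig), known)
  if (length(missing_ctg) > 0) {
    warning("contig(s) absent from GFF, classed intergenic: ",
            paste(missing_ctg, collapse = ", "))
  }
  snp <- GenomicRanges::GRanges(loci$contig,
                                IRanges::IRanges(loci$pos, loci$pos))
  GenomeInfoDb::seqlevels(snp) <-
    union(GenomeInfoDb::seqlevels(snp), GenomeInfoDb::seqlevels(genes))
  GenomeInfoDb::seqlevels(genes, pruning.mode = "coarse") <-
    GenomeInfoDb::seqlevels(snp)
  GenomeInfoDb::seqlevels(exons, pruning.mode = "coarse") <-
    GenomeInfoDb::seqlevels(snp)
  prom <- GenomicRanges::promoters(genes, upstream = promoter_bp,
                                   downstream = 0)
  gene_id <- as.character(S4Vectors::mcols(genes)$ID)

  hit_first <- function(subject) {
    ov <- GenomicRanges::findOverlaps(snp, subject, ignore.strand = TRUE)
    idx <- rep(NA_integer_, length(snp))
    idx[S4Vectors::queryHits(ov)[!duplicated(S4Vectors::queryHits(ov))]] <-
      S4Vectors::subjectHits(ov)[!duplicated(S4Vectors::queryHits(ov))]
    idx
  }
  in_exon <- hit_first(exons)
  in_gene <- hit_first(genes)
  in_prom <- hit_first(prom)

  context <- rep("intergenic", nrow(loci))
  gene <- rep("", nrow(loci))
  exon_parent <- as.character(S4Vectors::mcols(exons)$Parent)
  pick <- !is.na(in_prom) & is.na(in_gene)
  context[pick] <- "promoter"; gene[pick] <- gene_id[in_prom[pick]]
  pick <- !is.na(in_gene) & is.na(in_exon)
  context[pick] <- "intronic"; gene[pick] <- gene_id[in_gene[pick]]
  pick <- !is.na(in_exon)
  context[pick] <- "exonic"; gene[pick] <- exon_parent[in_exon[pick]]
  data.frame(locus_id = loci$locus_id, gene = gene, context = context,
             stringsAsFactors = FALSE)
}

#' GO-term over-representation among candidate loci (Fisher's exact test)
#'
#' For every GO term annotated to at least one background locus, a 2x2
#' table (candidate vs non-candidate x has-term vs not) is tested with a
#' two-sided exact test; Benjamini-Hochberg adjustment with flags at
#' adjusted p at most `q`.
#'
#' @param candidate_ids candidate locus ids (subset of `background_ids`).
#' @param background_ids the full filtered locus panel.
#' @param go_map data.frame: locus_id, go_terms (";"-separated, possibly
#'   empty).
#' @param q FDR level (study default 0.05).
#' @return data.frame per term: counts, odds_ratio, p, p_adj, flag.
#' @export
fisher_enrichment <- function(candidate_ids, background_ids, go_map,
                              q = 0.05) {
  stopifnot(all(candidate_ids %in% background_ids))
  gm <- go_map[go_map$locus_id %in% background_ids &
                 !is.na(go_map$go_terms) & go_map$go_terms != "", ]
  pairs <- data.frame(
    locus_id = rep(gm$locus_id, lengths(strsplit(gm$go_terms, ";"))),
    term = unlist(strsplit(gm$go_terms, ";")),
    stringsAsFactors = FALSE)
  pairs <- unique(pairs[pairs$term != "", ])
  if (nrow(pairs) == 0) {
    return(data.frame(term = character(), cand_with = integer(),
                      cand_without = integer(), bg_with = integer(),
                      bg_without = integer(), odds_ratio = numeric(),
                      p = numeric(), p_adj = numeric(), flag = logical()))
  }
  n_cand <- length(candidate_ids)
  n_bg <- length(background_ids)
  terms <- sort(unique(pairs$term))
  res <- lapply(terms, function(tm) {
    with_term <- pairs$locus_id[pairs$term == tm]
    a <- sum(candidate_ids %in% with_term)
    b <- n_cand - a
    cw <- length(with_term) - a            # non-candidate loci with term
    d <- (n_bg - n_cand) - cw
    ft <- stats::fisher.test(matrix(c(a, b, cw, d), 2))
    data.frame(term = tm, cand_with = a, cand_without = b,
               bg_with = cw, bg_without = d,
               odds_ratio = unname(ft$estimate),
               p = min(ft$p.value, 1),      # guard fp round-off above 1
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- fdr_adjust(out$p, method = "BH", q = q)
  out$p_adj <- adj$adjusted
  out$flag <- adj$flag
  out[order(out$p), , drop = FALSE]
}
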