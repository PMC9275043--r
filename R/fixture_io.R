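# On-disk fixture format: plain-text VCFv4.2 (GT only), CSVs with
# round-trip-exact doubles, an ESRI ASCII grid for the water mask, GFF3 gene
# models and a locus -> gene -> GO map.

#' Write a genotype matrix as a minimal VCFv4.2 file (GT only)
#'
#' @param G a [genotype_matrix()]; dosages are written as counts of the ALT
#'   allele, `NA` as `./.`.
#' @param path output file path.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  D <- G$dosage
  body <- vapply(seq_len(ncol(D)), function(j) {
    g <- D[, j]
    cells <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(G$loci$contig[j], G$loci$pos[j], G$locus_ids[j],
            G$loci$ref[j], G$loci$alt[j], ".", "PASS", ".", "GT", cells),
          collapse = "\t")
  }, character(1))
  contigs <- unique(G$loci$contig)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=seagea",
           sprintf("##contig=<ID=%s>", contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a water mask as an ESRI ASCII grid
#'
#' Water cells are written as 1, land as 0.
#' @param mask a [water_mask()].
#' @param path output path (conventionally `.asc`).
#' @export
write_mask_asc <- function(mask, path) {
  g <- mask$grid
  hdr <- c(sprintf("ncols %d", ncol(g)),
           sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %s", .fmt_num(mask$origin_lon)),
           sprintf("yllcorner %s", .fmt_num(mask$origin_lat)),
           sprintf("cellsize %s", .fmt_num(mask$cell_size)),
           "NODATA_value -9999")
  rows <- apply(g, 1, function(r) paste(as.integer(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a water mask from an ESRI ASCII grid
#'
#' Cells equal to 1 are water; 0 and NODATA are land.
#' @param path `.asc` file path.
#' @return a [water_mask()].
#' @export
read_water_mask <- function(path) {
  lines <- readLines(path)
  kv <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    kv[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  g <- do.call(rbind, vals)
  if (nrow(g) != kv$nrows || ncol(g) != kv$ncols) {
    stop("ASCII grid dimensions disagree with header")
  }
  nodata <- kv[["nodata_value"]] %||% -9999
  water_mask(!is.na(g) & g != nodata & g == 1,
             origin_lon = kv$xllcorner, origin_lat = kv$yllcorner,
             cell_size = kv$cellsize)
}

# synthetic gene models tiled along the fixture contigs: genes of 4 kb every
# 10 kb, alternating strand, two 800 bp exons at the gene ends
.make_gene_models <- function(loci) {
  rows <- list()
  for (ctg in unique(loci$contig)) {
    span <- max(loci$pos[loci$contig == ctg]) + 10000L
    starts <- seq(5001L, span, by = 10000L)
    for (k in seq_along(starts)) {
      gs <- starts[k]; ge <- gs + 3999L
      strand <- if (k %% 2 == 0) "-" else "+"
      gid <- sprintf("gene_%s_%03d", ctg, k)
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, type = "gene", start = gs, end = ge, strand = strand,
        id = gid, parent = NA_character_, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, type = "exon", start = gs, end = gs + 799L,
        strand = strand, id = paste0(gid, ".e1"), parent = gid,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, type = "exon", start = ge - 799L, end = ge,
        strand = strand, id = paste0(gid, ".e2"), parent = gid,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.write_gff3 <- function(models, path) {
  attrs <- ifelse(models$type == "gene",
                  sprintf("ID=%s", models$id),
                  sprintf("ID=%s;Parent=%s", models$id, models$parent))
  lines <- sprintf("%s\tseagea_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   models$contig, models$type, models$start, models$end,
                   models$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# locus -> gene -> GO map for the fixture: loci inside a gene inherit the
# gene's 1-3 GO terms (deterministic hash of the gene id); genes hosting
# adaptive loci additionally carry a shared "adaptive" term so that
# enrichment has signal to find
.make_go_map <- function(loci, truth, models) {
  genes <- models[models$type == "gene", ]
  pool <- sprintf("GO:%07d", 1:15)
  gene_of <- rep(NA_character_, nrow(loci))
  for (k in seq_len(nrow(genes))) {
    hit <- loci$contig == genes$contig[k] &
      loci$pos >= genes$start[k] & loci$pos <= genes$end[k]
    gene_of[hit] <- genes$id[k]
  }
  gene_terms <- function(gid, adaptive) {
    h <- sum(utf8ToInt(gid))
    terms <- pool[(h + 0:(h %% 3)) %% 15 + 1]
    if (adaptive) terms <- unique(c(terms, "GO:0009999"))
    paste(unique(terms), collapse = ";")
  }
  adaptive_gene <- unique(gene_of[truth$is_adaptive[match(loci$locus_id,
                                                          truth$locus_id)]])
  go <- vapply(seq_len(nrow(loci)), function(i) {
    if (is.na(gene_of[i])) "" else
      gene_terms(gene_of[i], gene_of[i] %in% adaptive_gene)
  }, character(1))
  data.frame(locus_id = loci$locus_id,
             gene = ifelse(is.na(gene_of), "", gene_of),
             go_terms = go, stringsAsFactors = FALSE)
}

#' Write a complete simulated study to disk
#'
#' Emits `genotypes.vcf`, `samples.csv`, `env.csv`, `mask.asc`,
#' `genes.gff3`, `go_map.csv` and `truth.csv`; [load_fixture()] re-reads
#' them into objects identical to the in-memory ones.
#'
#' @param sim result of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  G <- sim$genotypes
  write_vcf(G, file.path(outdir, "genotypes.vcf"))
  site <- attr(G, "site")
  samples <- sim$samples %||% data.frame(
    sample_id = G$sample_ids, site = site,
    lon = sim$sites$lon[match(site, sim$sites$site)],
    lat = sim$sites$lat[match(site, sim$sites$site)],
    stringsAsFactors = FALSE)
  .write_csv_exact(samples, file.path(outdir, "samples.csv"))
  .write_csv_exact(sim$env, file.path(outdir, "env.csv"))
  write_mask_asc(sim$mask, file.path(outdir, "mask.asc"))
  models <- .make_gene_models(G$loci)
  .write_gff3(models, file.path(outdir, "genes.gff3"))
  gm <- .make_go_map(G$loci, sim$truth, models)
  utils::write.csv(gm, file.path(outdir, "go_map.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth, file.path(outdir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(outdir)
}

#' Re-read a fixture written by [write_fixture()]
#'
#' @param outdir directory produced by [write_fixture()].
#' @return list with `genotypes`, `samples`, `env`, `mask`, `truth`,
#'   `go_map`, `gff_path`.
#' @export
load_fixture <- function(outdir) {
  samples <- utils::read.csv(file.path(outdir, "samples.csv"),
                             stringsAsFactors = FALSE)
  G <- load_genotypes(file.path(outdir, "genotypes.vcf"))
  attr(G, "site") <- samples$site[match(G$sample_ids, samples$sample_id)]
  list(genotypes = G,
       samples = samples,
       env = utils::read.csv(file.path(outdir, "env.csv"),
                             stringsAsFactors = FALSE),
       mask = read_water_mask(file.path(outdir, "mask.asc")),
       truth = utils::read.csv(file.path(outdir, "truth.csv"),
                               stringsAsFactors = FALSE),
       go_map = utils::read.csv(file.path(outdir, "go_map.csv"),
                                stringsAsFactors = FALSE,
                                colClasses = "character"),
       gff_path = file.path(outdir, "genes.gff3"))
}
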