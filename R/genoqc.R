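#' Genotype matrix container
#'
#' Individuals x loci minor-allele dosages in `{0,1,2}` with `NA` for
#' missing calls, plus sample ids and a locus table (contig, 1-based
#' position, ref/alt alleles; the alt column is always the counted,
#' globally-minor allele).
#'
#' @param dosage integer matrix individuals x loci.
#' @param sample_ids,locus_ids id vectors matching the matrix dimensions.
#' @param loci data.frame with columns locus_id, contig, pos, ref, alt.
#' @param site optional per-individual site labels (stored as an attribute).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, locus_ids, loci, site = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(dosage) == length(sample_ids),
            ncol(dosage) == length(locus_ids),
            !anyDuplicated(locus_ids),
            all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)),
            identical(loci$locus_id, locus_ids))
  dimnames(dosage) <- list(sample_ids, locus_ids)
  out <- structure(list(dosage = dosage, sample_ids = sample_ids,
                        locus_ids = locus_ids, loci = loci),
                   class = "genotype_matrix")
  if (!is.null(site)) {
    stopifnot(length(site) == length(sample_ids))
    attr(out, "site") <- site
  }
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Load a diploid biallelic SNP panel from a VCF
#'
#' Dosages count copies of the globally minor allele: loci where the ALT
#' allele frequency exceeds 0.5 are flipped (and their ref/alt columns
#' swapped so `alt` remains the counted allele). Multi-allelic and non-SNP
#' records are skipped with a message.
#'
#' @param vcf_path path to a VCFv4.x file with GT calls.
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    message(sprintf("load_genotypes: skipped %d multi-allelic/non-SNP records",
                    n_skip))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  alleles <- gsub("\\|", "/", gt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dose[alleles == "0/0"] <- 0L
  dose[alleles %in% c("0/1", "1/0")] <- 1L
  dose[alleles == "1/1"] <- 2L
  bad <- !is.na(alleles) & is.na(dose) &
    !(alleles %in% c("./.", ".", ".|."))
  if (any(bad)) stop("unrecognized GT value(s): ",
                     paste(utils::head(unique(alleles[bad])), collapse = ", "))
  dose <- t(dose)                             # individuals x loci
  ref <- fix$REF; alt <- fix$ALT
  for (j in seq_len(ncol(dose))) {
    obs <- dose[, j]
    n_obs <- sum(!is.na(obs))
    if (n_obs > 0 && sum(obs, na.rm = TRUE) > n_obs) {  # alt freq > 0.5
      dose[, j] <- 2L - dose[, j]
      tmp <- ref[j]; ref[j] <- alt[j]; alt[j] <- tmp
    }
  }
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, ":", fix$POS), ids)
  }
  genotype_matrix(dose, colnames(gt), ids,
                  data.frame(locus_id = ids, contig = fix$CHROM,
                             pos = as.integer(fix$POS), ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
}

# minor allele count per locus (copies of the rarer allele among observed)
.mac <- function(D) {
  s <- colSums(D, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(D))
  pmin(s, n2 - s)
}

.subset_gm <- function(G, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(G$dosage))
  cols <- cols %||% seq_len(ncol(G$dosage))
  site <- attr(G, "site")
  genotype_matrix(G$dosage[rows, cols, drop = FALSE],
                  G$sample_ids[rows], G$locus_ids[cols],
                  G$loci[cols, , drop = FALSE],
                  site = if (!is.null(site)) site[rows])
}

#' Locus-level filters: missingness and minor allele count
#'
#' Keeps loci whose missing fraction is at most `max_locus_missing` and
#' whose minor allele count (recomputed on the current individual set) is at
#' least `min_mac`. Order is preserved; the removed loci and reasons are
#' attached as `attr(,"removed")`.
#'
#' @param G a [genotype_matrix()].
#' @param max_locus_missing maximum tolerated missing fraction per locus.
#' @param min_mac minimum minor allele count (the study default is 3).
#' @return filtered [genotype_matrix()].
#' @export
filter_loci <- function(G, max_locus_missing = 0.2, min_mac = 3) {
  stopifnot(max_locus_missing >= 0, max_locus_missing <= 1, min_mac >= 0)
  D <- G$dosage
  miss <- colMeans(is.na(D))
  mac <- .mac(D)
  keep <- miss <= max_locus_missing & mac >= min_mac
  if (!any(keep)) stop("filter_loci: no loci left after filtering")
  out <- .subset_gm(G, cols = which(keep))
  attr(out, "removed") <- data.frame(
    locus_id = G$locus_ids[!keep],
    reason = ifelse(miss[!keep] > max_locus_missing, "missingness",
                    "mac")[seq_len(sum(!keep))],
    stringsAsFactors = FALSE)
  out
}

#' Individual-level missingness filter
#'
#' @param G a [genotype_matrix()].
#' @param max_ind_missing maximum tolerated missing fraction per individual.
#' @return filtered [genotype_matrix()].
#' @export
filter_individuals <- function(G, max_ind_missing = 0.5) {
  keep <- rowMeans(is.na(G$dosage)) <= max_ind_missing
  if (!any(keep)) stop("filter_individuals: no individuals left")
  out <- .subset_gm(G, rows = which(keep))
  attr(out, "removed") <- G$sample_ids[!keep]
  out
}

#' Pairwise relatedness from standardized allele sharing
#'
#' Moment estimator on dense biallelic panels: per locus, dosages are
#' standardized by the sample allele frequency, `w = (x - 2p) /
#' sqrt(2p(1-p))`, and relatedness of a pair is the mean of `w_i * w_j`
#' over their pairwise-complete loci (the genomic-relationship-matrix
#' estimator). Expectation ~1 for duplicates, ~0.5 for parent-offspring,
#' ~0 for unrelated pairs. Estimates are clipped to `[-1, 1]`; pairs with
#' fewer than `min_overlap` shared loci are `NA`.
#'
#' @param G a [genotype_matrix()].
#' @param min_overlap minimum pairwise-complete loci required (default 50).
#' @return symmetric individuals x individuals matrix (diagonal `NA`).
#' @export
pairwise_relatedness <- function(G, min_overlap = 50) {
  D <- G$dosage
  p <- colSums(D, na.rm = TRUE) / (2 * colSums(!is.na(D)))
  poly <- !is.na(p) & p > 0 & p < 1
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(D, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  M <- !is.na(W)
  Wz <- W; Wz[!M] <- 0
  num <- tcrossprod(Wz)
  den <- tcrossprod(M * 1)
  R <- num / den
  R[den < min_overlap] <- NA_real_
  R <- pmin(pmax(R, -1), 1)
  diag(R) <- NA_real_
  dimnames(R) <- list(G$sample_ids, G$sample_ids)
  R
}

#' Remove one individual per related pair
#'
#' Greedy pruning: while any pair has `|R| >= threshold`, remove the
#' individual involved in the most such pairs (ties broken by more missing
#' data, then lexicographically larger id).
#'
#' @param G a [genotype_matrix()].
#' @param R relatedness matrix aligned to `G` (see
#'   [pairwise_relatedness()]).
#' @param threshold removal threshold on `|R|` (the study used 0.5).
#' @return pruned [genotype_matrix()] with `attr(,"removed")` ids.
#' @export
prune_related <- function(G, R, threshold = 0.5) {
  stopifnot(identical(rownames(R), G$sample_ids))
  A <- !is.na(R) & abs(R) >= threshold
  diag(A) <- FALSE
  miss <- rowMeans(is.na(G$dosage))
  alive <- rep(TRUE, nrow(A))
  removed <- character()
  repeat {
    deg <- rowSums(A[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      cand <- cand[miss[cand] == max(miss[cand])]
      if (length(cand) > 1) {
        cand <- cand[order(G$sample_ids[cand])][1]
      }
    }
    alive[cand[1]] <- FALSE
    removed <- c(removed, G$sample_ids[cand[1]])
  }
  out <- .subset_gm(G, rows = which(alive))
  attr(out, "removed") <- removed
  out
}
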