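# End-to-end orchestration: QC -> spatial covariates -> environmental
# selection -> partial RDA GEA -> population structure -> enrichment, from
# one configuration, with per-stage derived seeds and a reproducible JSON
# report.

#' Pipeline configuration
#'
#' All thresholds default to the study's stated values: MAC < 3 removed,
#' relatedness |R| > 0.5, pairwise |r| > 0.7 and VIF >= 3 pruning, forward
#' selection at alpha 0.05 with 100 (spatial) / 1000 (environmental)
#' permutations, 1000-permutation ANOVA, +/-3SD candidate rule, 10,000
#' F_ST permutations with B-Y FDR < 10%, K 1-9 with ten CV replicates,
#' GO enrichment FDR <= 5%.
#'
#' @param vcf,samples,env,mask,gff,go_map,truth input file paths (gff,
#'   go_map and truth optional).
#' @param max_locus_missing,max_ind_missing missingness caps.
#' @param min_mac minor allele count threshold.
#' @param relatedness_threshold pruning threshold on |R|.
#' @param r_max,vif_max collinearity caps.
#' @param mem_alpha,mem_n_perm spatial forward selection.
#' @param env_alpha,env_n_perm environmental forward selection.
#' @param anova_n_perm permutations for the RDA ANOVA.
#' @param sd_mult candidate threshold in SD units.
#' @param fst_n_perm,fst_q F_ST permutations and FDR level.
#' @param k_range candidate cluster numbers.
#' @param k_method `"AIC"` or `"CV"`.
#' @param enrich_q enrichment FDR level.
#' @param promoter_bp promoter window for context classification.
#' @param spatial_mode `"individual"` (default; distances and spatial
#'   eigenvectors computed between individual sampling coordinates, as the
#'   GPS-per-individual design implies) or `"centroid"` (site centroids,
#'   expanded to individuals).
#' @param seed global seed; stage streams are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, samples, env, mask = NULL, gff = NULL,
                            go_map = NULL, truth = NULL,
                            max_locus_missing = 0.2, max_ind_missing = 0.5,
                            min_mac = 3, relatedness_threshold = 0.5,
                            r_max = 0.7, vif_max = 3,
                            mem_alpha = 0.05, mem_n_perm = 100,
                            env_alpha = 0.05, env_n_perm = 1000,
                            anova_n_perm = 1000, sd_mult = 3,
                            fst_n_perm = 10000, fst_q = 0.10,
                            k_range = 1:9, k_method = "AIC",
                            enrich_q = 0.05, promoter_bp = 2000,
                            spatial_mode = c("individual", "centroid"),
                            seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$k_range) && length(vals$k_range) == 2) {
    vals$k_range <- seq(vals$k_range[1], vals$k_range[2])
  }
  do.call(pipeline_config, vals)
}

#' Run the full seascape genomics pipeline
#'
#' Stages in study order: genotype QC (individual missingness, relatedness
#' pruning, then locus missingness and MAC filters), oceanic distances and
#' dbMEM construction with forward selection, environmental
#' standardization / collinearity pruning / forward selection, partial RDA
#' with permutation ANOVA and +/-3SD candidate detection with Spearman
#' predictor assignment, candidate-based diversity / F_ST / PCA /
#' clustering, and GO enrichment. Identical config and inputs give an
#' identical report.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory for artifacts and `report.json`.
#' @return the report, invisibly (also written to `outdir`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema = "seagea-report/1",
                 config = config[!vapply(config, is.null, logical(1))])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- load -----------------------------------------------------------
  G <- stage("load", load_genotypes(config$vcf))
  samples <- utils::read.csv(config$samples, stringsAsFactors = FALSE)
  stopifnot(all(G$sample_ids %in% samples$sample_id))
  samples <- samples[match(G$sample_ids, samples$sample_id), ]
  attr(G, "site") <- samples$site
  env_tab <- utils::read.csv(config$env, stringsAsFactors = FALSE)
  report$input <- list(individuals = nrow(G$dosage),
                       loci = ncol(G$dosage))

  # ---- qc -------------------------------------------------------------
  qc <- stage("qc", {
    G1 <- filter_individuals(G, config$max_ind_missing)
    R <- pairwise_relatedness(G1)
    G2 <- prune_related(G1, R, threshold = config$relatedness_threshold)
    G3 <- filter_loci(G2, max_locus_missing = config$max_locus_missing,
                      min_mac = config$min_mac)
    list(G = G3,
         removed_individuals = c(attr(G1, "removed"), attr(G2, "removed")),
         removed_loci = nrow(attr(G3, "removed")))
  })
  G <- qc$G
  samples <- samples[match(G$sample_ids, samples$sample_id), ]
  report$qc <- list(individuals = nrow(G$dosage), loci = ncol(G$dosage),
                    removed_individuals = qc$removed_individuals,
                    removed_loci = qc$removed_loci)

  site <- attr(G, "site")
  site_levels <- unique(site)
  Y <- impute_dosage(G)

  # ---- environment table (standardize + collinearity prune) ----------
  env_prep <- stage("environment", {
    if ("sample_id" %in% names(env_tab)) {
      Ei <- env_tab[match(G$sample_ids, env_tab$sample_id), , drop = FALSE]
      Ei$sample_id <- NULL
    } else {
      stopifnot("site" %in% names(env_tab))
      Ei <- env_tab[match(site, env_tab$site), , drop = FALSE]
      Ei$site <- NULL
    }
    Es <- standardize_env(Ei)
    kept <- collinearity_prune(Es, r_max = config$r_max,
                               vif_max = config$vif_max)
    list(Es = Es, kept = kept)
  })
  Es <- env_prep$Es

  # ---- spatial: MEMs conditioned on the candidate environment ---------
  spat <- stage("spatial", {
    if (identical(config$spatial_mode, "centroid")) {
      pts <- stats::aggregate(cbind(lon, lat) ~ site, data = samples, mean)
      pts <- pts[match(site_levels, pts$site), ]
    } else {
      pts <- samples[, c("sample_id", "lon", "lat")]
    }
    if (!is.null(config$mask)) {
      mask <- read_water_mask(config$mask)
      D <- oceanic_distances(pts, mask)
    } else {
      D <- geosphere::distm(as.matrix(pts[, c("lon", "lat")])) / 1000
    }
    basis <- build_dbmem(D)
    mems <- if (identical(config$spatial_mode, "centroid")) {
      expand_mem(basis, site, site_levels)
    } else basis$vectors
    sel <- forward_select_mems(Y, mems, alpha = config$mem_alpha,
                               n_perm = config$mem_n_perm, Z = Es,
                               seed = derive_seed(config$seed, "mem"))
    list(D = D, basis = basis, mems = mems, sel = sel)
  })
  mem_idx <- spat$sel$selected
  Z <- if (length(mem_idx) > 0) spat$mems[, mem_idx, drop = FALSE] else NULL
  report$spatial <- list(
    truncation_km = spat$basis$truncation,
    n_mems = ncol(spat$basis$vectors),
    selected_mems = colnames(spat$basis$vectors)[mem_idx],
    global_p = spat$sel$global_p)

  # ---- environmental forward selection (conditioned on the MEMs) -----
  envs <- stage("env_selection", {
    sel <- forward_select_env(Y, Es[, env_prep$kept, drop = FALSE], Z = Z,
                              alpha = config$env_alpha,
                              n_perm = config$env_n_perm,
                              seed = derive_seed(config$seed, "env"))
    list(Es = Es, kept = env_prep$kept, sel = sel)
  })
  retained <- envs$sel$retained
  report$environment <- list(n_input = ncol(envs$Es),
                             kept_after_collinearity = envs$kept,
                             retained = retained,
                             global_p = envs$sel$global_p)

  # ---- gea ------------------------------------------------------------
  if (length(retained) == 0) {
    report$gea <- list(note = "no environmental variable retained",
                       n_candidates = 0)
    candidates <- data.frame()
  } else {
    gea <- stage("gea", {
      X <- envs$Es[, retained, drop = FALSE]
      model <- partial_rda(Y, X, Z)
      seed_a <- derive_seed(config$seed, "anova")
      overall <- permutation_significance(model, "overall",
                                          n_perm = config$anova_n_perm,
                                          seed = seed_a)
      terms <- permutation_significance(model, "term",
                                        n_perm = config$anova_n_perm,
                                        seed = seed_a)
      axes <- permutation_significance(model, "axis",
                                       n_perm = config$anova_n_perm,
                                       seed = seed_a)
      sig_axes <- which(axes$p <= 0.05)
      cand <- if (length(sig_axes) > 0) {
        detect_candidates(model, sig_axes, sd_mult = config$sd_mult)
      } else data.frame()
      if (nrow(cand) > 0) {
        cand <- assign_predictors(cand, G, envs$Es[, retained, drop = FALSE])
      }
      list(model = model, overall = overall, terms = terms, axes = axes,
           sig_axes = sig_axes, cand = cand)
    })
    candidates <- gea$cand
    axis_share <- gea$model$eigenvalues / sum(gea$model$eigenvalues)
    report$gea <- list(
      partition = as.list(gea$model$partition),
      overall_p = gea$overall$p,
      term_p = stats::setNames(as.list(gea$terms$p), gea$terms$term),
      axis_p = stats::setNames(as.list(gea$axes$p), gea$axes$term),
      axis_share_constrained = as.numeric(axis_share),
      significant_axes = gea$sig_axes,
      n_candidates = nrow(candidates))
    if (nrow(candidates) > 0) {
      .write_csv_exact(candidates, file.path(outdir, "candidates.csv"))
    }
  }

  # ---- structure (on candidate loci) ---------------------------------
  if (nrow(candidates) >= 2) {
    str_res <- stage("structure", {
      Gc <- .subset_gm(G, cols = match(candidates$locus_id, G$locus_ids))
      div <- diversity_by_site(Gc, site)
      fst <- pairwise_fst(Gc, site, n_perm = config$fst_n_perm,
                          q = config$fst_q,
                          seed = derive_seed(config$seed, "fst"))
      pca <- genotype_pca(impute_dosage(Gc))
      kc <- choose_k(Gc, k_range = config$k_range,
                     method = config$k_method,
                     seed = derive_seed(config$seed, "k"))
      best <- em_cluster(Gc, kc$best_k,
                         seed = derive_seed(config$seed, "em_best"))
      list(div = div, fst = fst, pca = pca, kc = kc, best = best)
    })
    .write_csv_exact(str_res$div, file.path(outdir, "diversity.csv"))
    .write_csv_exact(as.data.frame(str_res$fst$theta),
                     file.path(outdir, "fst.csv"))
    report$structure <- list(
      diversity = str_res$div,
      fst = list(theta = str_res$fst$theta, p = str_res$fst$p,
                 significant = str_res$fst$significant),
      pca_var_explained = utils::head(str_res$pca$var_explained, 5),
      k_table = str_res$kc$table,
      best_k = str_res$kc$best_k)
  } else {
    report$structure <- list(note = "too few candidates for structure analysis")
  }

  # ---- enrichment -----------------------------------------------------
  if (!is.null(config$gff) && !is.null(config$go_map) &&
      nrow(candidates) > 0) {
    enr <- stage("enrichment", {
      ctx <- classify_context(
        G$loci[match(candidates$locus_id, G$locus_ids), , drop = FALSE],
        config$gff, promoter_bp = config$promoter_bp)
      gm <- utils::read.csv(config$go_map, stringsAsFactors = FALSE,
                            colClasses = "character")
      tab <- fisher_enrichment(candidates$locus_id, G$locus_ids, gm,
                               q = config$enrich_q)
      list(ctx = ctx, tab = tab)
    })
    report$enrichment <- list(
      context_counts = as.list(table(enr$ctx$context)),
      n_terms_tested = nrow(enr$tab),
      flagged_terms = enr$tab$term[enr$tab$flag])
    if (nrow(enr$tab) > 0) {
      utils::write.csv(enr$tab, file.path(outdir, "enrichment.csv"),
                       row.names = FALSE)
    }
  } else {
    report$enrichment <- list(note = "enrichment skipped")
  }

  # ---- truth recovery -------------------------------------------------
  if (!is.null(config$truth)) {
    truth <- utils::read.csv(config$truth, stringsAsFactors = FALSE)
    planted <- truth$locus_id[truth$is_adaptive & truth$locus_id %in%
                                G$locus_ids]
    flagged <- if (nrow(candidates) > 0) candidates$locus_id else character()
    report$recovery <- list(
      n_planted_surviving_qc = length(planted),
      n_flagged = length(flagged),
      n_true_positive = sum(flagged %in% planted),
      sensitivity = if (length(planted) > 0)
        sum(flagged %in% planted) / length(planted) else NA,
      false_flag_fraction = if (length(flagged) > 0)
        mean(!(flagged %in% planted)) else NA)
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  writeLines(json, file.path(outdir, "report.json"))
  invisible(report)
}
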