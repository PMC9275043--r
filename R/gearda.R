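# Genotype-environment association by partial redundancy analysis (RDA):
# ordination of the genotype matrix constrained by environmental predictors
# while conditioning on spatial eigenvectors, permutation ANOVA,
# +/-3SD outlier detection on constrained axes, and Spearman assignment of
# the best environmental predictor per candidate locus.

#' Mean-impute and centre a dosage matrix for ordination
#'
#' Missing entries are replaced by the locus mean dosage over observed
#' individuals (so the locus mean is preserved exactly); columns are then
#' centred.
#'
#' @param G a [genotype_matrix()].
#' @return dense numeric individuals x loci matrix with column means 0.
#' @export
impute_dosage <- function(G) {
  D <- G$dosage * 1.0
  mu <- colMeans(D, na.rm = TRUE)
  if (anyNA(mu) || any(!is.finite(mu))) {
    stop("locus with all genotypes missing: ",
         paste(G$locus_ids[!is.finite(mu)], collapse = ", "))
  }
  idx <- which(is.na(D), arr.ind = TRUE)
  if (nrow(idx) > 0) D[idx] <- mu[idx[, 2]]
  sweep(D, 2, mu, "-")
}

#' Partial redundancy analysis of a genotype matrix
#'
#' Constrained ordination: the (imputed, centred) genotype response `Y` and
#' the predictors `X` are residualized on the conditioners `Z` by least
#' squares; the residual response is regressed on the residual predictors
#' and the fitted values eigendecomposed. Locus loadings use a
#' species-score scaling proportional to eigenvector times the square root
#' of the axis eigenvalue; candidate z-scores downstream are invariant to
#' this choice.
#'
#' @param Y numeric individuals x loci matrix (see [impute_dosage()]).
#' @param X environmental predictors (individuals x variables).
#' @param Z optional conditioning matrix (e.g., selected MEMs); `NULL` for
#'   an unconditioned RDA.
#' @return object of class `rda_model`: eigenvalues (descending),
#'   `loadings` (loci x axes, scaled), `axes` (unit locus eigenvectors),
#'   `scores` (individual scores, residual `Y` projected on the unit
#'   eigenvectors), `biplot` (predictor correlations with fitted-site
#'   scores), and `partition` (conditioned / constrained / residual
#'   fractions of total genotype variance).
#' @export
partial_rda <- function(Y, X, Z = NULL) {
  Y <- .center(as.matrix(Y))
  X <- .center(as.matrix(X))
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  tot <- sum(Y^2)

  Qz <- NULL; r <- 0L; ss_cond <- 0
  Yr <- Y; Xr <- X
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Z <- .center(as.matrix(Z))
    stopifnot(nrow(Z) == n)
    Qz <- .qr_basis(Z)
    r <- ncol(Qz)
    ss_cond <- sum(crossprod(Qz, Y)^2)
    Yr <- Y - Qz %*% crossprod(Qz, Y)
    Xr <- X - Qz %*% crossprod(Qz, X)
  }
  qx0 <- qr(X)
  if (qx0$rank < ncol(X)) {
    bad <- colnames(X)[qx0$pivot[(qx0$rank + 1):ncol(X)]]
    stop("rank-deficient predictors (collinear columns): ",
         paste(bad, collapse = ", "))
  }
  # predictors absorbed by the conditioners are aliased: dropped, so that
  # e.g. Z = X leaves a model with zero constrained axes
  scale0 <- sqrt(colSums(X^2))
  aliased <- sqrt(colSums(Xr^2)) < 1e-8 * pmax(scale0, 1)
  Xr <- Xr[, !aliased, drop = FALSE]
  if (ncol(Xr) == 0) {
    Qx <- matrix(0, n, 0)
  } else {
    qx <- qr(Xr)
    Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  }
  C <- crossprod(Qx, Yr)                   # q x L
  if (nrow(C) > 0) {
    sv <- svd(C)
    lambda <- sv$d^2 / (n - 1)
    keep <- lambda > max(lambda[1], 1e-300) * 1e-12
    lambda <- lambda[keep]
    V <- sv$v[, keep, drop = FALSE]        # unit locus eigenvectors
  } else {
    lambda <- numeric(0)
    V <- matrix(0, ncol(Yr), 0)
  }
  ax <- sprintf("RDA%d", seq_along(lambda))
  colnames(V) <- ax
  rownames(V) <- colnames(Y)
  loadings <- sweep(V, 2, sqrt(lambda), "*")
  scores <- Yr %*% V                       # individual ("wa"-style) scores
  lc <- (Qx %*% C) %*% V                   # fitted-site scores
  biplot <- suppressWarnings(stats::cor(Xr, lc))
  ss_constr <- sum(C^2)
  partition <- c(conditioned = ss_cond / tot,
                 constrained = ss_constr / tot,
                 residual = (tot - ss_cond - ss_constr) / tot)
  structure(list(
    eigenvalues = lambda, loadings = loadings, axes = V, scores = scores,
    lc_scores = lc, biplot = biplot, partition = partition,
    n = n, q = ncol(Qx), r = r, tot_ss = tot,
    Y = Y, X = X, Z = Z, Qx = Qx, Qz = Qz, Yr = Yr,
    predictor_names = colnames(X)
  ), class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("partial RDA: %d individuals, %d loci, %d predictors, %d conditioners\n",
              x$n, ncol(x$Y), x$q, x$r))
  cat(sprintf("variance partition: conditioned %.3f, constrained %.3f, residual %.3f\n",
              x$partition[1], x$partition[2], x$partition[3]))
  invisible(x)
}

#' Permutation ANOVA for a (partial) RDA model
#'
#' Pseudo-F tests by permutation of the residuals of the reduced model (the
#' conditioning variables are held fixed). `scope = "overall"` tests the
#' whole constrained fraction; `"term"` tests each predictor marginally
#' (conditioning on the other predictors and `Z`); `"axis"` tests
#' constrained axes sequentially (prior axes added to the conditioners).
#' p-values are `(exceedances + 1) / (n_perm + 1)`.
#'
#' @param model an `rda_model`.
#' @param scope one of `"overall"`, `"term"`, `"axis"`.
#' @param n_perm number of permutations (study default 1000).
#' @param seed integer seed.
#' @return data.frame with columns term, statistic (pseudo-F), p, n_perm.
#' @export
permutation_significance <- function(model, scope = c("overall", "term", "axis"),
                                     n_perm = 1000, seed = 1L) {
  scope <- match.arg(scope)
  if (n_perm < 1) stop("n_perm must be at least 1")
  set.seed(derive_seed(seed, paste0("anova_", scope)))
  n <- model$n
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)

  if (scope == "overall") {
    q <- model$q; r <- model$r
    df_res <- n - 1 - r - q
    ss_constr <- model$partition["constrained"] * model$tot_ss
    ss_res <- model$partition["residual"] * model$tot_ss
    f_obs <- (ss_constr / q) / (ss_res / df_res)
    # permute rows of the Z-residualized response; refit both blocks
    Qjoint <- cbind(model$Qz, model$Qx)
    ss <- .perm_proj_ss(Qjoint, model$Yr, perms)
    r_z <- model$r
    ssz <- if (r_z > 0) rowSums(ss[, seq_len(r_z), drop = FALSE]) else 0
    ssx <- rowSums(ss[, (r_z + 1):(r_z + q), drop = FALSE])
    tot_r <- sum(model$Yr^2)
    f_b <- (ssx / q) / ((tot_r - ssz - ssx) / df_res)
    p <- (sum(f_b >= f_obs) + 1) / (n_perm + 1)
    return(data.frame(term = "model", statistic = f_obs, p = p,
                      n_perm = n_perm, stringsAsFactors = FALSE))
  }

  if (scope == "term") {
    out <- lapply(seq_len(ncol(model$X)), function(j) {
      Zj <- cbind(model$Z, model$X[, -j, drop = FALSE])
      .partial_f_test(model$Y, model$X[, j, drop = FALSE], Zj, perms,
                      label = model$predictor_names[j])
    })
    return(do.call(rbind, out))
  }

  # scope == "axis": sequential tests, prior axes conditioned out
  out <- list()
  for (a in seq_along(model$eigenvalues)) {
    Za <- cbind(model$Z,
                if (a > 1) model$lc_scores[, seq_len(a - 1), drop = FALSE])
    out[[a]] <- .axis_f_test(model$Y, model$X, Za, perms,
                             label = sprintf("RDA%d", a))
  }
  do.call(rbind, out)
}

# marginal pseudo-F test of predictor block X1 given conditioners Z1
.partial_f_test <- function(Y, X1, Z1, perms, label) {
  n <- nrow(Y)
  Qz <- if (!is.null(Z1) && ncol(as.matrix(Z1)) > 0)
    .qr_basis(.center(as.matrix(Z1))) else matrix(0, n, 0)
  r <- ncol(Qz)
  Yr <- Y - if (r > 0) Qz %*% crossprod(Qz, Y) else 0
  X1r <- .center(as.matrix(X1))
  if (r > 0) X1r <- X1r - Qz %*% crossprod(Qz, X1r)
  Qx <- .qr_basis(X1r)
  q <- ncol(Qx)
  df_res <- n - 1 - r - q
  ssx <- sum(crossprod(Qx, Yr)^2)
  tot_r <- sum(Yr^2)
  f_obs <- (ssx / q) / ((tot_r - ssx) / df_res)
  ss <- .perm_proj_ss(cbind(Qz, Qx), Yr, perms)
  ssz_b <- if (r > 0) rowSums(ss[, seq_len(r), drop = FALSE]) else 0
  ssx_b <- rowSums(ss[, (r + 1):(r + q), drop = FALSE])
  f_b <- (ssx_b / q) / ((tot_r - ssz_b - ssx_b) / df_res)
  p <- (sum(f_b >= f_obs) + 1) / (length(perms) + 1)
  data.frame(term = label, statistic = f_obs, p = p, n_perm = length(perms),
             stringsAsFactors = FALSE)
}

# first-axis pseudo-F test of X given conditioners Z1 (for sequential axis
# tests): statistic is the leading eigenvalue over the residual mean square
.axis_f_test <- function(Y, X, Z1, perms, label) {
  n <- nrow(Y)
  Qz <- if (!is.null(Z1) && ncol(as.matrix(Z1)) > 0)
    .qr_basis(.center(as.matrix(Z1))) else matrix(0, n, 0)
  r <- ncol(Qz)
  Yr <- Y - if (r > 0) Qz %*% crossprod(Qz, Y) else 0
  Xr <- .center(as.matrix(X))
  if (r > 0) Xr <- Xr - Qz %*% crossprod(Qz, Xr)
  Qx <- .qr_basis(Xr)
  q <- ncol(Qx)
  if (q == 0) {
    return(data.frame(term = label, statistic = NA_real_, p = NA_real_,
                      n_perm = length(perms), stringsAsFactors = FALSE))
  }
  df_res <- n - 1 - r - q
  top_ss <- function(M) {
    cp <- tcrossprod(M)                    # q x q
    max(eigen((cp + t(cp)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  }
  C <- crossprod(Qx, Yr)
  l1 <- top_ss(C)
  ss_res <- sum(Yr^2) - sum(C^2)
  f_obs <- l1 / (ss_res / df_res)
  f_b <- vapply(perms, function(pm) {
    Yp <- Yr[pm, , drop = FALSE]
    if (r > 0) Yp <- Yp - Qz %*% crossprod(Qz, Yp)
    Cp <- crossprod(Qx, Yp)
    l1p <- top_ss(Cp)
    (l1p) / ((sum(Yp^2) - sum(Cp^2)) / df_res)
  }, numeric(1))
  p <- (sum(f_b >= f_obs) + 1) / (length(perms) + 1)
  data.frame(term = label, statistic = f_obs, p = p, n_perm = length(perms),
             stringsAsFactors = FALSE)
}

#' Detect candidate outlier loci on significant constrained axes
#'
#' Per axis, locus loadings are converted to z-scores (mean and SD over all
#' loci); loci with `|z| >= sd_mult` are flagged. A locus extreme on
#' several axes is reported once, on the axis of its largest `|z|`.
#'
#' @param model an `rda_model`.
#' @param significant_axes integer vector of constrained-axis indices.
#' @param sd_mult the threshold in SD units (study default 3).
#' @return data.frame: locus_id, axis, loading, z.
#' @export
detect_candidates <- function(model, significant_axes, sd_mult = 3) {
  stopifnot(length(significant_axes) >= 1,
            all(significant_axes %in% seq_along(model$eigenvalues)))
  rows <- list()
  ids <- rownames(model$loadings) %||% sprintf("locus%d", nrow(model$loadings))
  for (a in significant_axes) {
    load <- model$loadings[, a]
    s <- stats::sd(load)
    if (s < 1e-300) {
      warning(sprintf("axis %d has zero loading SD; no candidates from it", a))
      next
    }
    z <- (load - mean(load)) / s
    hit <- which(abs(z) >= sd_mult)
    if (length(hit) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      locus_id = ids[hit], axis = a, loading = load[hit], z = z[hit],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(), axis = integer(),
                      loading = numeric(), z = numeric()))
  }
  all <- do.call(rbind, rows)
  all <- all[order(-abs(all$z)), ]
  all <- all[!duplicated(all$locus_id), ]
  all[order(match(all$locus_id, ids)), , drop = FALSE]
}

#' Assign the best environmental predictor to each candidate locus
#'
#' Spearman rank correlation (average ranks for ties) between the observed
#' (non-imputed) dosages of each candidate and every retained environmental
#' variable over pairwise-complete individuals; the predictor with the
#' largest `|rho|` is reported with its two-sided p-value.
#'
#' @param candidates data.frame from [detect_candidates()].
#' @param G a [genotype_matrix()] aligned with the model individuals.
#' @param E_retained individuals x retained-variables matrix.
#' @return `candidates` with best_predictor, spearman_rho, spearman_p.
#' @export
assign_predictors <- function(candidates, G, E_retained) {
  E <- as.matrix(E_retained)
  vars <- colnames(E) %||% paste0("v", seq_len(ncol(E)))
  best <- character(nrow(candidates))
  rho <- numeric(nrow(candidates)); pv <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x <- G$dosage[, candidates$locus_id[i]]
    if (stats::sd(x, na.rm = TRUE) < 1e-300 || sum(!is.na(x)) < 3) {
      warning("constant or near-empty dosage vector for ",
              candidates$locus_id[i])
      best[i] <- "none"; rho[i] <- NA_real_; pv[i] <- NA_real_
      next
    }
    rhos <- vapply(seq_len(ncol(E)), function(j)
      suppressWarnings(stats::cor(x, E[, j], method = "spearman",
                                  use = "pairwise.complete.obs")),
      numeric(1))
    jb <- which.max(abs(rhos))
    best[i] <- vars[jb]
    rho[i] <- rhos[jb]
    pv[i] <- suppressWarnings(
      stats::cor.test(x, E[, jb], method = "spearman",
                      exact = FALSE)$p.value)
  }
  candidates$best_predictor <- best
  candidates$spearman_rho <- rho
  candidates$spearman_p <- pv
  candidates
}
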