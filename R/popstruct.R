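# Population diversity and structure: per-site heterozygosity, pairwise
# Weir-Cockerham F_ST with permutation tests and B-Y FDR correction, PCA,
# and an EM binomial-mixture clustering with AIC / cross-validation choice
# of the number of clusters.

#' Observed and expected heterozygosity by site
#'
#' Ho is the mean (over loci) fraction of heterozygotes; He is the mean
#' unbiased expected heterozygosity `2p(1-p) * 2n/(2n-1)` with `n` diploids
#' observed at the site. Loci with fewer than two genotyped individuals at
#' a site are skipped for that site.
#'
#' @param G a [genotype_matrix()].
#' @param site per-individual site labels (defaults to `attr(G, "site")`).
#' @return data.frame: site, N (individuals), Ho, He.
#' @export
diversity_by_site <- function(G, site = attr(G, "site")) {
  stopifnot(!is.null(site), length(site) == nrow(G$dosage))
  out <- lapply(unique(site), function(s) {
    D <- G$dosage[site == s, , drop = FALSE]
    n <- colSums(!is.na(D))
    ok <- n >= 2
    het <- colMeans(D == 1, na.rm = TRUE)[ok]
    p <- (colSums(D, na.rm = TRUE) / (2 * n))[ok]
    he <- 2 * p * (1 - p) * (2 * n[ok]) / (2 * n[ok] - 1)
    data.frame(site = s, N = nrow(D), Ho = mean(het), He = mean(he),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Weir-Cockerham (1984) variance components for one set of sites.
# Inputs are per-site per-locus matrices: n (diploids observed), p (allele
# frequency), h (heterozygote frequency). Returns summed a and a+b+c.
.wc_components <- function(n, p, h) {
  r <- nrow(n)
  ok <- colSums(n >= 1) == r & colSums(n) > r   # every site observed
  n <- n[, ok, drop = FALSE]; p <- p[, ok, drop = FALSE]
  h <- h[, ok, drop = FALSE]
  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  fin <- is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = sum(a[fin]), abc = sum((a + b + cc)[fin]))
}

#' Multilocus Weir-Cockerham theta for a set of sites
#'
#' Ratio-of-sums estimator: per-locus variance components a, b, c are
#' summed over loci before forming `theta = sum(a) / sum(a+b+c)`.
#'
#' @param G a [genotype_matrix()] or plain dosage matrix.
#' @param site per-individual site labels.
#' @return scalar theta.
#' @export
wc_theta <- function(G, site) {
  D <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  lv <- unique(site)
  stopifnot(length(lv) >= 2)
  L <- ncol(D)
  n <- t(vapply(lv, function(s)
    colSums(!is.na(D[site == s, , drop = FALSE])), numeric(L)))
  sm <- t(vapply(lv, function(s)
    colSums(D[site == s, , drop = FALSE], na.rm = TRUE), numeric(L)))
  ht <- t(vapply(lv, function(s)
    colSums(D[site == s, , drop = FALSE] == 1, na.rm = TRUE), numeric(L)))
  if (L == 1) { n <- t(n); sm <- t(sm); ht <- t(ht) }
  p <- sm / (2 * n); h <- ht / n
  p[!is.finite(p)] <- 0; h[!is.finite(h)] <- 0
  comp <- .wc_components(n, p, h)
  comp$a / comp$abc
}

# vectorized two-site theta for B permuted splits of a pooled dosage matrix:
# S1 is a B x n_pool 0/1 membership matrix for site 1
.theta_two_site_batch <- function(D, S1) {
  M <- (!is.na(D)) * 1
  Dz <- D; Dz[is.na(Dz)] <- 0
  H <- (D == 1) * 1; H[is.na(H)] <- 0
  tot_n <- colSums(M); tot_s <- colSums(Dz); tot_h <- colSums(H)
  n1 <- S1 %*% M; s1 <- S1 %*% Dz; h1 <- S1 %*% H
  n2 <- sweep(-n1, 2, tot_n, "+")
  s2 <- sweep(-s1, 2, tot_s, "+")
  h2 <- sweep(-h1, 2, tot_h, "+")
  p1 <- s1 / (2 * n1); p2 <- s2 / (2 * n2)
  hf1 <- h1 / n1; hf2 <- h2 / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * hf1 + n2 * hf2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  abc <- a + b + cc
  bad <- !is.finite(a) | !is.finite(abc) | n1 < 1 | n2 < 1 | nbar <= 1
  a[bad] <- 0; abc[bad] <- 0
  rowSums(a) / rowSums(abc)
}

#' Pairwise Weir-Cockerham F_ST with permutation tests and B-Y correction
#'
#' For every site pair, the multilocus theta and a one-sided permutation
#' p-value (individuals shuffled between the two sites,
#' `p = (exceedances + 1) / (n_perm + 1)`); Benjamini-Yekutieli step-up
#' adjustment across all pairs at FDR `q`.
#'
#' @param G a [genotype_matrix()].
#' @param site per-individual site labels.
#' @param n_perm permutations per pair (study default 10000).
#' @param q FDR level (study default 0.10).
#' @param seed integer seed.
#' @return object of class `fst_result`: `theta`, `p`, `p_adj`,
#'   `significant` matrices.
#' @export
pairwise_fst <- function(G, site = attr(G, "site"), n_perm = 10000,
                         q = 0.10, seed = 1L) {
  D <- G$dosage
  lv <- unique(site)
  sizes <- table(factor(site, levels = lv))
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding site(s) with < 2 individuals: ",
            paste(small, collapse = ", "))
    lv <- setdiff(lv, small)
  }
  stopifnot(length(lv) >= 2)
  set.seed(derive_seed(seed, "fst"))
  k <- length(lv)
  theta <- matrix(0, k, k, dimnames = list(lv, lv))
  pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rows <- which(site %in% c(lv[i], lv[j]))
      Dp <- D[rows, , drop = FALSE] * 1.0
      is1 <- site[rows] == lv[i]
      n1 <- sum(is1); np <- length(rows)
      obs <- .theta_two_site_batch(Dp, matrix(as.numeric(is1), 1))
      S1 <- matrix(0, n_perm, np)
      for (b in seq_len(n_perm)) S1[b, sample.int(np, n1)] <- 1
      perm <- .theta_two_site_batch(Dp, S1)
      theta[i, j] <- theta[j, i] <- obs
      pmat[i, j] <- pmat[j, i] <- (sum(perm >= obs) + 1) / (n_perm + 1)
    }
  }
  up <- upper.tri(pmat)
  adj <- fdr_adjust(pmat[up], method = "BY", q = q)
  p_adj <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  sig <- matrix(NA, k, k, dimnames = list(lv, lv))
  p_adj[up] <- adj$adjusted; sig[up] <- adj$flag
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  structure(list(theta = theta, p = pmat, p_adj = p_adj, significant = sig,
                 n_perm = n_perm, q = q), class = "fst_result")
}

#' Step-up false-discovery-rate adjustment (BH or B-Y)
#'
#' Thin wrapper over [stats::p.adjust()]: Benjamini-Hochberg or
#' Benjamini-Yekutieli (the latter multiplies by the harmonic sum
#' `c(m) = sum(1/i)`), with flags at adjusted p at most `q`.
#'
#' @param p vector of p-values.
#' @param method `"BY"` or `"BH"`.
#' @param q FDR level for the flags.
#' @return list: `adjusted`, `flag`.
#' @export
fdr_adjust <- function(p, method = c("BY", "BH"), q = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0) return(list(adjusted = numeric(), flag = logical()))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adjusted <- stats::p.adjust(p, method = method)
  list(adjusted = adjusted, flag = !is.na(adjusted) & adjusted <= q)
}

#' Principal component analysis of an imputed genotype matrix
#'
#' Eigendecomposition (via SVD) of the centred matrix; axes ordered by
#' eigenvalue with explained-variance fractions.
#'
#' @param Y centred individuals x loci matrix (see [impute_dosage()]).
#' @param n_axes number of axes to return (default all).
#' @return list: `scores`, `eigenvalues`, `var_explained`.
#' @export
genotype_pca <- function(Y, n_axes = NULL) {
  Y <- .center(as.matrix(Y))
  sv <- svd(Y)
  ev <- sv$d^2 / (nrow(Y) - 1)
  k <- min(n_axes %||% length(ev), sum(sv$d > 1e-9 * sv$d[1]))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(scores) <- rownames(Y)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  list(scores = scores, eigenvalues = ev[seq_len(k)],
       var_explained = ev / sum(ev))
}

# one EM run from a random start; returns freqs, memberships, logL path
.em_run <- function(Xz, M, K, max_iter, tol) {
  n <- nrow(Xz); L <- ncol(Xz)
  R <- matrix(stats::runif(n * K), n, K)
  R <- R / rowSums(R)
  pi_k <- rep(1 / K, K)
  clamp <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
  P <- clamp((crossprod(R, Xz)) / (2 * crossprod(R, M)))
  ll_path <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    LL <- Xz %*% t(log(P)) + (2 * M - Xz) %*% t(log(1 - P))
    LL <- sweep(LL, 2, log(pi_k), "+")
    mx <- apply(LL, 1, max)
    lse <- mx + log(rowSums(exp(LL - mx)))
    ll <- sum(lse)
    R <- exp(LL - lse)
    pi_k <- pmax(colMeans(R), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    P <- clamp((crossprod(R, Xz)) / pmax(2 * crossprod(R, M), 1e-12))
    ll_path <- c(ll_path, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(P = P, R = R, pi = pi_k, logL = ll, logL_path = ll_path)
}

#' Maximum-likelihood mixture clustering of genotypes by EM
#'
#' Finite mixture with cluster-specific allele frequencies and binomial
#' genotype likelihoods under within-cluster Hardy-Weinberg proportions.
#' EM is run to a log-likelihood tolerance of 1e-6 (at most `max_iter`
#' iterations), best of `n_restarts` random starts. Soft memberships are
#' returned; `AIC = -2 logL + 2 K L` counts the `K x L` allele frequencies
#' as parameters.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param K number of clusters.
#' @param seed integer seed.
#' @param n_restarts random restarts (default 10).
#' @param max_iter EM iteration cap.
#' @return object of class `cluster_result`: K, membership, freqs, logL,
#'   logL_path, AIC.
#' @export
em_cluster <- function(G, K, seed = 1L, n_restarts = 10, max_iter = 500) {
  D <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  n <- nrow(D); L <- ncol(D)
  if (K > n) stop("K exceeds the number of individuals")
  stopifnot(K >= 1)
  M <- (!is.na(D)) * 1
  Xz <- D * 1.0; Xz[is.na(Xz)] <- 0
  const <- sum(D == 1, na.rm = TRUE) * log(2)   # log choose(2, x)
  set.seed(derive_seed(seed, sprintf("em_K%d", K)))
  best <- NULL
  for (rs in seq_len(max(1, if (K == 1) 1 else n_restarts))) {
    run <- .em_run(Xz, M, K, max_iter, tol = 1e-6)
    if (is.null(best) || run$logL > best$logL) best <- run
  }
  logL <- best$logL + const
  structure(list(K = K,
                 membership = best$R,
                 freqs = best$P,
                 mixing = best$pi,
                 logL = logL,
                 logL_path = best$logL_path + const,
                 AIC = -2 * logL + 2 * K * L),
            class = "cluster_result")
}

#' Choose the number of clusters by AIC or masked-entry cross-validation
#'
#' AIC mode: fit [em_cluster()] for each K; best K minimizes AIC. CV mode:
#' per replicate, 10% of the non-missing genotype entries are masked
#' uniformly at random, the model is fitted on the rest, and the mean
#' squared error of predicting the masked dosages from memberships times
#' cluster frequencies is scored; best K minimizes the mean CV error.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param k_range candidate K values (study default 1-9).
#' @param method `"AIC"` or `"CV"`.
#' @param cv_replicates masked replicates per K (study default 10).
#' @param cv_mask masked fraction of observed entries.
#' @param seed integer seed.
#' @param n_restarts EM restarts for the AIC fits.
#' @param cv_restarts EM restarts inside CV replicates.
#' @return list: `table` (per-K scores), `best_k`, `method`, `fits` (AIC
#'   mode only).
#' @export
choose_k <- function(G, k_range = 1:9, method = c("AIC", "CV"),
                     cv_replicates = 10, cv_mask = 0.1, seed = 1L,
                     n_restarts = 10, cv_restarts = 3) {
  method <- match.arg(method)
  D <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  k_range <- k_range[k_range <= nrow(D)]
  if (method == "AIC") {
    fits <- lapply(k_range, function(K)
      em_cluster(D, K, seed = seed, n_restarts = n_restarts))
    tab <- data.frame(K = k_range,
                      logL = vapply(fits, `[[`, numeric(1), "logL"),
                      AIC = vapply(fits, `[[`, numeric(1), "AIC"))
    return(list(table = tab, best_k = k_range[which.min(tab$AIC)],
                method = "AIC", fits = fits))
  }
  set.seed(derive_seed(seed, "choose_k_cv"))
  obs_idx <- which(!is.na(D))
  err <- matrix(NA_real_, length(k_range), cv_replicates)
  for (rep_i in seq_len(cv_replicates)) {
    mask <- sample(obs_idx, max(1, round(cv_mask * length(obs_idx))))
    Dm <- D; Dm[mask] <- NA
    truth <- D[mask]
    for (ki in seq_along(k_range)) {
      fit <- em_cluster(Dm, k_range[ki],
                        seed = derive_seed(seed, sprintf("cv_%d_%d",
                                                         rep_i, k_range[ki])),
                        n_restarts = cv_restarts)
      pred_full <- fit$membership %*% (2 * fit$freqs)
      err[ki, rep_i] <- mean((pred_full[mask] - truth)^2)
    }
  }
  tab <- data.frame(K = k_range, cv_error = rowMeans(err))
  list(table = tab, best_k = k_range[which.min(tab$cv_error)],
       method = "CV", cv_errors = err)
}
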