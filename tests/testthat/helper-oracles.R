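# Independent oracles used across tests. These deliberately avoid the
# package's own linear-algebra paths: explicit projection matrices via
# solve(), dense eigendecompositions, scalar loops.

# brute-force (partial) RDA: explicit hat matrices and a dense eigensolver
brute_rda <- function(Y, X, Z = NULL) {
  Y <- scale(Y, scale = FALSE)
  X <- scale(X, scale = FALSE)
  n <- nrow(Y)
  tot <- sum(Y^2)
  ss_cond <- 0
  if (!is.null(Z)) {
    Z <- scale(as.matrix(Z), scale = FALSE)
    Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
    ss_cond <- sum((Hz %*% Y)^2)
    Y <- Y - Hz %*% Y
    X <- X - Hz %*% X
  }
  Hx <- X %*% solve(crossprod(X)) %*% t(X)
  F <- Hx %*% Y
  ev <- eigen(crossprod(F), symmetric = TRUE)
  lambda <- ev$values / (n - 1)
  keep <- lambda > 1e-12 * max(lambda)
  list(eigenvalues = lambda[keep],
       vectors = ev$vectors[, keep, drop = FALSE],
       partition = c(conditioned = ss_cond / tot,
                     constrained = sum(F^2) / tot,
                     residual = (tot - ss_cond - sum(F^2)) / tot))
}

# Weir-Cockerham (1984) variance components for one biallelic locus,
# written as scalar arithmetic straight from the definitions
wc_locus_oracle <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# theta from a dosage matrix + labels, via the per-locus scalar oracle
wc_theta_oracle <- function(D, site) {
  lv <- unique(site)
  num <- 0; den <- 0
  for (l in seq_len(ncol(D))) {
    n_i <- p_i <- h_i <- numeric(length(lv))
    for (s in seq_along(lv)) {
      g <- D[site == lv[s], l]
      g <- g[!is.na(g)]
      n_i[s] <- length(g)
      p_i[s] <- if (length(g)) sum(g) / (2 * length(g)) else NA
      h_i[s] <- if (length(g)) mean(g == 1) else NA
    }
    if (any(n_i < 1) || mean(n_i) <= 1) next
    comp <- wc_locus_oracle(n_i, p_i, h_i)
    if (all(is.finite(comp))) {
      num <- num + comp["a"]; den <- den + sum(comp)
    }
  }
  unname(num / den)
}

# two-sided Fisher p by exhaustive hypergeometric tail enumeration
fisher_oracle <- function(a, b, c0, d) {
  m <- a + c0; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small genotype_matrix from a plain dosage matrix
tiny_gm <- function(D, site = NULL) {
  D <- as.matrix(D)
  L <- ncol(D)
  ids <- sprintf("L%03d", seq_len(L))
  genotype_matrix(D, sprintf("i%03d", seq_len(nrow(D))), ids,
                  data.frame(locus_id = ids, contig = "chr1",
                             pos = 1000L * seq_len(L),
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  site = site)
}

# Hardy-Weinberg dosage matrix at given allele frequencies
hw_matrix <- function(n, freqs) {
  matrix(stats::rbinom(n * length(freqs), 2, rep(freqs, each = n)), nrow = n)
}
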