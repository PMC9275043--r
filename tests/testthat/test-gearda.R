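# Partial RDA core: imputation, ordination against a brute-force oracle
# (and vegan as an independent cross-check), permutation ANOVA, +/-3SD
# outlier detection, Spearman predictor assignment.

test_that("mean imputation preserves locus means and centres columns", {
  G <- tiny_gm(cbind(c(0L, 2L, NA), c(1L, 1L, 1L)))
  Y <- impute_dosage(G)
  expect_equal(unname(Y[, 1]), c(-1, 1, 0))
  expect_equal(unname(colSums(Y)), c(0, 0), tolerance = 1e-10)

  G2 <- tiny_gm(cbind(c(NA, NA, NA), c(0L, 1L, 2L)))
  expect_error(impute_dosage(G2), "all genotypes missing")
})

test_that("partial RDA matches the brute-force oracle on random small instances", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(8:16, 1)
    L <- sample(5:20, 1)
    q <- sample(2:3, 1)
    Y <- matrix(rnorm(n * L), n, L)
    X <- matrix(rnorm(n * q), n, q)
    Z <- if (rep %% 2 == 0) matrix(rnorm(n * 2), n, 2) else NULL
    m <- partial_rda(Y, X, Z)
    o <- brute_rda(Y, X, Z)
    expect_equal(m$eigenvalues, o$eigenvalues, tolerance = 1e-8)
    expect_equal(unname(m$partition), unname(o$partition), tolerance = 1e-8)
    # loadings equal the oracle eigenvectors up to sign, scaled by
    # sqrt(eigenvalue)
    for (a in seq_along(m$eigenvalues)) {
      v <- m$loadings[, a] / sqrt(m$eigenvalues[a])
      expect_equal(abs(sum(v * o$vectors[, a])), 1, tolerance = 1e-8)
    }
  }
})

test_that("partial RDA agrees with vegan's constrained ordination", {
  skip_if_not_installed("vegan")
  set.seed(12)
  n <- 30; L <- 40
  Y <- matrix(rnorm(n * L), n, L)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("m1", "m2")))
  m <- partial_rda(Y, X, Z)
  df <- data.frame(X, Z)
  vg <- vegan::rda(Y ~ a + b + c + Condition(m1 + m2), data = df)
  expect_equal(unname(m$eigenvalues),
               unname(vg$CCA$eig), tolerance = 1e-6)
  expect_equal(unname(m$partition["conditioned"]),
               vg$pCCA$tot.chi / vg$tot.chi, tolerance = 1e-8)
  expect_equal(unname(m$partition["constrained"]),
               vg$CCA$tot.chi / vg$tot.chi, tolerance = 1e-8)
})

test_that("degenerate geometries: perfect fit, null fit, fully conditioned", {
  set.seed(13)
  n <- 50; L <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  # exact linear response: everything constrained
  Yx <- X %*% matrix(rnorm(2 * L), 2, L)
  m1 <- partial_rda(Yx, X)
  expect_equal(unname(m1$partition["constrained"]), 1, tolerance = 1e-10)
  expect_equal(unname(m1$partition["residual"]), 0, tolerance = 1e-10)

  # independent response: constrained fraction at chance level
  Y0 <- matrix(rnorm(n * L), n, L)
  m2 <- partial_rda(Y0, X)
  expect_lt(m2$partition["constrained"], 2 * 2 / n)

  # conditioning away the predictors leaves nothing to constrain
  m3 <- partial_rda(Y0 + X %*% matrix(rnorm(2 * L), 2, L), X, Z = X)
  expect_equal(unname(m3$partition["constrained"]), 0)
  expect_length(m3$eigenvalues, 0)

  expect_error(partial_rda(Y0, cbind(X, X[, 1])), "collinear")
})

test_that("individual scores are the residual response projected on the axes", {
  set.seed(14)
  Y <- matrix(rnorm(40 * 25), 40, 25)
  X <- matrix(rnorm(40 * 3), 40, 3)
  Z <- matrix(rnorm(40 * 2), 40, 2)
  m <- partial_rda(Y, X, Z)
  expect_equal(m$scores, m$Yr %*% m$axes, tolerance = 1e-8)
})

test_that("permutation ANOVA is deterministic, calibrated, and saturates on strong signal", {
  set.seed(15)
  n <- 60; L <- 50
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- matrix(rnorm(n * L), n, L)
  m <- partial_rda(Y, X)
  a1 <- permutation_significance(m, "overall", n_perm = 99, seed = 4)
  a2 <- permutation_significance(m, "overall", n_perm = 99, seed = 4)
  expect_identical(a1, a2)
  expect_gt(a1$p, 0.05)   # null data: typically insignificant

  Ys <- Y + X %*% matrix(rnorm(2 * L, 0, 1.5), 2, L)
  ms <- partial_rda(Ys, X)
  as <- permutation_significance(ms, "overall", n_perm = 99, seed = 4)
  expect_equal(as$p, 1 / 100)

  terms <- permutation_significance(ms, "term", n_perm = 99, seed = 4)
  expect_equal(nrow(terms), 2)
  expect_true(all(terms$p <= 0.05))
  axes <- permutation_significance(ms, "axis", n_perm = 99, seed = 4)
  expect_equal(axes$term, c("RDA1", "RDA2"))

  expect_error(permutation_significance(ms, "overall", n_perm = 0), "n_perm")
})

test_that("outlier detection flags exactly the planted extreme locus", {
  set.seed(16)
  load <- c(rnorm(999), 5)
  model <- structure(list(
    loadings = matrix(load, ncol = 1,
                      dimnames = list(sprintf("L%04d", 1:1000), "RDA1")),
    eigenvalues = 1), class = "rda_model")
  cand <- detect_candidates(model, 1, sd_mult = 3)
  z <- (load - mean(load)) / sd(load)
  expect_setequal(cand$locus_id, sprintf("L%04d", which(abs(z) >= 3)))
  expect_true("L1000" %in% cand$locus_id)

  expect_equal(nrow(detect_candidates(model, 1, sd_mult = 0)), 1000)

  const <- structure(list(
    loadings = matrix(rep(1, 10), ncol = 1,
                      dimnames = list(sprintf("L%03d", 1:10), "RDA1")),
    eigenvalues = 1), class = "rda_model")
  expect_warning(out <- detect_candidates(const, 1), "zero loading SD")
  expect_equal(nrow(out), 0)
})

test_that("a locus extreme on two axes is reported once, on its larger-|z| axis", {
  set.seed(17)
  L1 <- c(rnorm(500), 6, 5)
  L2 <- c(rnorm(500), 4, 8)
  model <- structure(list(
    loadings = cbind(RDA1 = L1, RDA2 = L2), eigenvalues = c(2, 1)),
    class = "rda_model")
  rownames(model$loadings) <- sprintf("L%04d", 1:502)
  cand <- detect_candidates(model, 1:2)
  expect_equal(sum(cand$locus_id == "L0502"), 1)
  expect_equal(cand$axis[cand$locus_id == "L0502"], 2)
  expect_equal(cand$axis[cand$locus_id == "L0501"], 1)
})

test_that("Spearman assignment picks the driving variable with textbook rho", {
  G <- tiny_gm(cbind(c(1L, 2L, NA, 1L, 0L, 2L),
                     c(0L, 1L, 2L, 2L, 1L, 0L)))
  E <- cbind(mono = c(2, 4, 6, 8, 10, 12),
             noise = c(0.3, -1, 2, 0.1, -0.4, 0.9))
  cand <- data.frame(locus_id = c("L001", "L002"), axis = 1,
                     loading = 1, z = 3.5, stringsAsFactors = FALSE)
  out <- assign_predictors(cand, G, E)
  expect_true(all(c("best_predictor", "spearman_rho", "spearman_p") %in%
                    names(out)))

  # untied monotone dosage: rho exactly 1, invariant under monotone maps
  G2 <- tiny_gm(matrix(c(0L, 1L, 2L), ncol = 1))
  E2 <- cbind(v = c(2, 4, 6))
  c2 <- data.frame(locus_id = "L001", axis = 1, loading = 1, z = 3.5)
  expect_equal(assign_predictors(c2, G2, E2)$spearman_rho, 1)
  expect_equal(assign_predictors(c2, G2, cbind(v = exp(E2[, 1])))$spearman_rho, 1)

  # hand-computed average-rank rho for a tied 6-vector
  x <- c(0, 1, 1, 2, 2, 2)
  e <- c(1.1, 0.9, 2.0, 2.5, 2.4, 3.0)
  rx <- rank(x); re <- rank(e)
  rho_hand <- sum((rx - mean(rx)) * (re - mean(re))) /
    sqrt(sum((rx - mean(rx))^2) * sum((re - mean(re))^2))
  G3 <- tiny_gm(matrix(as.integer(x), ncol = 1))
  c3 <- assign_predictors(data.frame(locus_id = "L001", axis = 1,
                                     loading = 1, z = 3.5),
                          G3, cbind(v = e))
  expect_equal(c3$spearman_rho, rho_hand, tolerance = 1e-12)

  # constant dosage: no predictor, warning
  G4 <- tiny_gm(matrix(c(1L, 1L, 1L, 1L), ncol = 1))
  expect_warning(
    c4 <- assign_predictors(data.frame(locus_id = "L001", axis = 1,
                                       loading = 1, z = 3.5),
                            G4, cbind(v = 1:4)), "constant")
  expect_equal(c4$best_predictor, "none")
})
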