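# Population diversity and structure: heterozygosity, Weir-Cockerham theta
# against scalar oracles, permutation F_ST, FDR adjustment, PCA, EM mixture
# clustering and K selection.

test_that("heterozygosities match closed forms", {
  # all-heterozygote site of 4: Ho = 1, p = 0.5, unbiased He = (8/7) * 0.5
  G <- tiny_gm(matrix(c(1L, 1L, 1L, 1L), ncol = 1), site = rep("A", 4))
  div <- diversity_by_site(G)
  expect_equal(div$Ho, 1)
  expect_equal(div$He, 0.5 * 8 / 7)

  # monomorphic locus: both zero
  G0 <- tiny_gm(matrix(0L, 4, 1), site = rep("A", 4))
  div0 <- diversity_by_site(G0)
  expect_equal(div0$Ho, 0)
  expect_equal(div0$He, 0)

  # Hardy-Weinberg at p = 0.3: Ho ~ He ~ 0.42 within sampling error
  set.seed(21)
  Gh <- tiny_gm(hw_matrix(500, rep(0.3, 60)), site = rep("A", 500))
  divh <- diversity_by_site(Gh)
  expect_lt(abs(divh$Ho - 0.42), 0.02)
  expect_lt(abs(divh$He - 0.42), 0.02)
})

test_that("Weir-Cockerham theta matches the scalar oracle on toys", {
  # the two-site toy: site A 10 ref-hom; site B 5 ref-hom + 5 het
  D <- matrix(c(rep(0L, 10), rep(0L, 5), rep(1L, 5)), ncol = 1)
  site <- rep(c("A", "B"), each = 10)
  th <- wc_theta(D, site)
  comp <- wc_locus_oracle(n_i = c(10, 10), p_i = c(0, 0.25),
                          h_i = c(0, 0.5))
  expect_equal(th, unname(comp["a"] / sum(comp)), tolerance = 1e-10)

  # three sites, two loci, missing data: oracle loops over loci
  set.seed(22)
  D2 <- hw_matrix(30, c(0.2, 0.7))
  D2[c(3, 17)] <- NA
  site2 <- rep(c("A", "B", "C"), each = 10)
  expect_equal(wc_theta(D2, site2), wc_theta_oracle(D2, site2),
               tolerance = 1e-10)

  # fixed difference: theta = 1 exactly
  Df <- matrix(c(rep(0L, 8), rep(2L, 8)), ncol = 1)
  expect_equal(wc_theta(Df, rep(c("A", "B"), each = 8)), 1)

  # identical frequencies: theta near zero
  set.seed(23)
  Dn <- hw_matrix(100, runif(1000, 0.1, 0.9))
  expect_lt(abs(wc_theta(Dn, rep(c("A", "B"), each = 50))), 0.01)
})

test_that("pairwise F_ST permutation test accepts the null and flags true structure", {
  set.seed(24)
  freqs <- runif(300, 0.2, 0.8)
  null_pops <- tiny_gm(hw_matrix(60, freqs),
                       site = rep(c("A", "B", "C"), each = 20))
  f0 <- pairwise_fst(null_pops, n_perm = 199, seed = 3)
  expect_true(all(f0$p[upper.tri(f0$p)] > 0.05))
  expect_true(all(abs(f0$theta[upper.tri(f0$theta)]) < 0.02))
  expect_equal(f0$theta, t(f0$theta))

  # strongly diverged pair is detected and B-Y flagged
  set.seed(25)
  pa <- hw_matrix(25, runif(300, 0.05, 0.3))
  pb <- hw_matrix(25, runif(300, 0.7, 0.95))
  div_pops <- tiny_gm(rbind(pa, pb), site = rep(c("A", "B"), each = 25))
  f1 <- pairwise_fst(div_pops, n_perm = 199, q = 0.10, seed = 3)
  expect_equal(f1$p["A", "B"], 1 / 200)
  expect_true(f1$significant["A", "B"])
})

test_that("F_ST permutation p-values are uniform under the null", {
  set.seed(26)
  p_vals <- replicate(120, {
    D <- hw_matrix(24, runif(60, 0.2, 0.8))
    f <- pairwise_fst(tiny_gm(D, site = rep(c("A", "B"), each = 12)),
                      n_perm = 49, seed = sample.int(1e6, 1))
    f$p["A", "B"]
  })
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH and BY adjustments match step-up formula oracles", {
  expect_equal(fdr_adjust(0.03, "BY")$adjusted, 0.03)

  bh <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), "BH")
  expect_equal(bh$adjusted, rep(0.04, 4))

  p <- c(0.001, 0.01, 0.02, 0.04, 0.05)
  by <- fdr_adjust(p, "BY", q = 0.10)
  cm <- sum(1 / (1:5))                       # 137/60
  # step-up with the harmonic factor, monotone from the largest p down
  raw <- p * 5 * cm / seq_along(p)
  oracle <- rev(cummin(rev(pmin(raw, 1))))
  expect_equal(by$adjusted, oracle)
  expect_equal(by$adjusted[1], 0.001 * 5 * 137 / 60)

  # BY flags are a subset of BH flags at equal q
  set.seed(27)
  pr <- runif(50)^2
  f_by <- fdr_adjust(pr, "BY", q = 0.1)$flag
  f_bh <- fdr_adjust(pr, "BH", q = 0.1)$flag
  expect_true(all(!f_by | f_bh))

  expect_length(fdr_adjust(numeric(), "BY")$adjusted, 0)
})

test_that("PCA separates populations and preserves geometry", {
  set.seed(28)
  fa <- runif(200, 0.1, 0.9)
  shift <- pmin(pmax(fa + runif(200, -0.4, 0.4), 0.02), 0.98)
  D <- rbind(hw_matrix(30, fa), hw_matrix(30, shift))
  Y <- impute_dosage(tiny_gm(D))
  pca <- genotype_pca(Y)
  labels <- rep(0:1, each = 30)
  expect_gt(abs(cor(pca$scores[, 1], labels)), 0.9)

  # full-rank scores reproduce pairwise distances of the centred data
  expect_equal(as.matrix(dist(pca$scores)), as.matrix(dist(Y)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # a duplicated individual lands on coincident coordinates
  D2 <- rbind(D, D[1, ])
  Y2 <- impute_dosage(tiny_gm(D2))
  p2 <- genotype_pca(Y2)
  expect_equal(p2$scores[1, ], p2$scores[61, ], tolerance = 1e-8)
})

test_that("EM clustering: single-component likelihood is closed form and logL climbs", {
  set.seed(29)
  D <- hw_matrix(40, runif(80, 0.2, 0.8))
  D[sample(length(D), 50)] <- NA
  fit1 <- em_cluster(D, K = 1, seed = 5)
  expect_equal(rowSums(fit1$membership), rep(1, 40))
  # closed form: pooled frequencies, binomial log-likelihood
  p_hat <- colSums(D, na.rm = TRUE) / (2 * colSums(!is.na(D)))
  p_hat <- pmin(pmax(p_hat, 1e-4), 1 - 1e-4)
  ll <- 0
  for (j in seq_len(ncol(D))) {
    x <- D[!is.na(D[, j]), j]
    ll <- ll + sum(dbinom(x, 2, p_hat[j], log = TRUE))
  }
  expect_equal(fit1$logL, ll, tolerance = 1e-6)
  expect_equal(fit1$AIC, -2 * ll + 2 * ncol(D))

  fit3 <- em_cluster(D, K = 3, seed = 5, n_restarts = 3)
  expect_true(all(diff(fit3$logL_path) > -1e-6))
  expect_equal(rowSums(fit3$membership), rep(1, 40), tolerance = 1e-8)

  expect_error(em_cluster(D, K = 41), "exceeds")
})

test_that("two diverged populations are assigned with high accuracy", {
  set.seed(30)
  fa <- runif(100, 0.2, 0.8)
  fb <- pmin(pmax(fa + sample(c(-1, 1), 100, TRUE) * 0.35, 0.02), 0.98)
  D <- rbind(hw_matrix(30, fa), hw_matrix(30, fb))
  fit <- em_cluster(D, K = 2, seed = 6)
  hard <- max.col(fit$membership)
  truth <- rep(1:2, each = 30)
  acc <- max(mean(hard == truth), mean(hard == 3 - truth))
  expect_gte(acc, 0.95)
})

test_that("AIC table is recomputable and K selection finds planted structure", {
  set.seed(31)
  freqs <- replicate(3, runif(120, 0.05, 0.95))
  D <- do.call(rbind, lapply(1:3, function(k) hw_matrix(20, freqs[, k])))
  ck <- choose_k(D, k_range = 1:5, method = "AIC", seed = 7, n_restarts = 5)
  expect_equal(ck$table$AIC, -2 * ck$table$logL + 2 * ck$table$K * 120)
  expect_equal(ck$best_k, 3)

  cv <- choose_k(D, k_range = 1:5, method = "CV", cv_replicates = 5,
                 seed = 7, cv_restarts = 2)
  expect_equal(cv$best_k, 3)

  # homogeneous data: one cluster wins
  D1 <- hw_matrix(40, runif(120, 0.2, 0.8))
  ck1 <- choose_k(D1, k_range = 1:4, method = "AIC", seed = 8,
                  n_restarts = 5)
  expect_equal(ck1$best_k, 1)
})

test_that("candidate loci out-differentiate neutral loci between env-extreme sites", {
  sim <- shared_sim()
  G <- sim$genotypes
  site <- attr(G, "site")
  # environmentally extreme site pair for the first gradient
  v <- sim$env[[2]]
  ends <- sim$env$site[c(which.min(v), which.max(v))]
  keep <- site %in% ends
  ad <- sim$truth$is_adaptive[match(G$locus_ids, sim$truth$locus_id)]
  th_ad <- wc_theta(G$dosage[keep, ad], site[keep])
  th_ne <- wc_theta(G$dosage[keep, !ad], site[keep])
  expect_gt(th_ad, th_ne)
})
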