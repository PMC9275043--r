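# Synthetic seascape generator: gradients, correlations, stepping-stone
# calibration, adaptive clines, planted relatives, fixture round trips.

test_that("noise-free gradients are monotone and duplicated gradients correlate perfectly", {
  cfg <- sim_config(n_sites = 9,
                    env_vars = list(v1 = list(shape = "linear", noise_sd = 0)),
                    seed = 3)
  sea <- make_seascape(cfg)
  ord <- order(sea$sites$s)
  expect_true(all(diff(sea$env$v1[ord]) > 0))

  cfg2 <- sim_config(n_sites = 9,
                     env_vars = list(v1 = list(shape = "linear", noise_sd = 0),
                                     v2 = list(shape = "sigmoid", noise_sd = 0)),
                     env_correlation = matrix(c(1, 1, 1, 1), 2),
                     seed = 3)
  sea2 <- make_seascape(cfg2)
  expect_equal(cor(sea2$env$v1, sea2$env$v2), 1, tolerance = 1e-10)
})

test_that("realized correlation approaches the target as prescribed", {
  cfg <- sim_config(n_sites = 50, per_site_n = 2,
                    env_vars = list(a = list(shape = "linear", noise_sd = 0.1),
                                    b = list(shape = "sine", noise_sd = 0.1)),
                    env_correlation = matrix(c(1, 0.8, 0.8, 1), 2),
                    seed = 11)
  sea <- make_seascape(cfg)
  # oracle: textbook Pearson r computed directly on the emitted table
  x <- sea$env$a; y <- sea$env$b
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cor(x, y), r_direct, tolerance = 1e-12)
  expect_lt(abs(r_direct - 0.8), 0.1)
})

test_that("zero effect size makes 'adaptive' loci indistinguishable from neutral", {
  # neutral drift is set to the study's weak lower bound so that the
  # comparison isolates the effect-size term
  cfg <- sim_config(n_neutral = 500, n_adaptive = 500, effect_size = 0,
                    drift_fst = 0.001, per_site_n = 12, seed = 5)
  sea <- make_seascape(cfg)
  sim <- simulate_genotypes(sea$sites, sea$env, cfg)
  site <- attr(sim$genotypes, "site")
  z <- scale(sea$env$sst_min)[match(site, sea$sites$site)]
  cors <- suppressWarnings(
    cor(sim$genotypes$dosage, z, use = "pairwise.complete.obs"))
  is_ad <- sim$truth$is_adaptive
  ks <- suppressWarnings(stats::ks.test(cors[is_ad], cors[!is_ad]))
  expect_gt(ks$p.value, 0.01)
})

test_that("neutral differentiation is calibrated to the target F_ST", {
  sim <- shared_sim()   # drift_fst = 0.02, 200 individuals, 2000 neutral loci
  G <- sim$genotypes
  neutral <- sim$truth$locus_id[!sim$truth$is_adaptive]
  th <- wc_theta(G$dosage[seq_len(200), match(neutral, G$locus_ids)],
                 attr(G, "site")[seq_len(200)])
  expect_gt(th, 0.01)
  expect_lt(th, 0.04)
})

test_that("adaptive site frequencies follow the logistic cline in the effect size", {
  # 3 sites, noise-free linear gradient: standardized driver is (-1, 0, 1),
  # so the logit of the site frequency must climb by 2b from end to end
  cfg <- sim_config(n_sites = 3, per_site_n = 150, n_neutral = 0,
                    n_adaptive = 60, effect_size = 2,
                    env_vars = list(v = list(shape = "linear", noise_sd = 0)),
                    missing_rate = 0, seed = 9)
  sea <- make_seascape(cfg)
  z <- scale(sea$env$v)[, 1]
  sim <- simulate_genotypes(sea$sites, sea$env, cfg)
  site <- attr(sim$genotypes, "site")
  D <- sim$genotypes$dosage
  p1 <- colMeans(D[site == "S01", ]) / 2
  p3 <- colMeans(D[site == "S03", ]) / 2
  # coding may flip allele per locus; use |logit difference|; the logistic
  # model implies a logit change of b * (z_3 - z_1) end to end
  dl <- abs(qlogis(pmin(pmax(p3, 0.01), 0.99)) -
            qlogis(pmin(pmax(p1, 0.01), 0.99)))
  expected <- cfg$effect_size * (z[3] - z[1])
  # binomial noise at n=150 gives SE(logit) ~ 0.2 per end
  expect_lt(abs(mean(dl) - expected), 0.35)
})

test_that("planted relatives copy their source and are caught by relatedness", {
  sim <- shared_sim()
  G0 <- simulate_genotypes(sim$sites, sim$env, sim$config)$genotypes
  expect_identical(plant_relatives(G0, 0)$dosage, G0$dosage)

  Gp <- plant_relatives(G0, 3, seed = 17, missing_rate = 0.01)
  expect_equal(nrow(Gp$dosage), nrow(G0$dosage) + 3)
  pp <- attr(Gp, "planted_pairs")
  expect_equal(nrow(pp), 3)
  for (k in 1:3) {
    src <- Gp$dosage[pp$source[k], ]
    dup <- Gp$dosage[pp$duplicate[k], ]
    obs <- !is.na(src) & !is.na(dup)
    expect_true(all(src[obs] == dup[obs]))
  }
  R <- pairwise_relatedness(Gp)
  expect_true(all(R[cbind(pp$source, pp$duplicate)] >= 0.9))
})

test_that("fixture round-trips bit-identically and the VCF keeps its contract", {
  sim <- shared_sim()
  out <- withr::local_tempdir()
  write_fixture(sim, out)
  back <- load_fixture(out)
  expect_identical(back$genotypes$dosage, sim$genotypes$dosage)
  expect_identical(back$genotypes$locus_ids, sim$genotypes$locus_ids)
  expect_identical(back$samples$lon, sim$samples$lon)
  expect_identical(back$env[[2]], sim$env[[2]])
  expect_identical(back$mask$grid, sim$mask$grid)
  expect_equal(nrow(back$truth),
               sim$config$n_neutral + sim$config$n_adaptive)

  vcf <- readLines(file.path(out, "genotypes.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  expect_equal(length(body), ncol(sim$genotypes$dosage))
  gt <- unlist(lapply(strsplit(body, "\t"), function(x) x[-(1:9)]))
  expect_true(all(grepl("^([01]/[01]|\\./\\.)$", gt)))
})

test_that("identical configuration and seed reproduce the simulation exactly", {
  cfg <- sim_config(n_neutral = 150, n_adaptive = 10, per_site_n = 5,
                    seed = 23)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$env, b$env)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
})

test_that("stronger selection strengthens the dosage-environment correlation", {
  m_abs_rho <- sapply(c(0, 0.5, 1, 2), function(b) {
    cfg <- sim_config(n_neutral = 5, n_adaptive = 40, per_site_n = 12,
                      effect_size = b, missing_rate = 0, seed = 31)
    sea <- make_seascape(cfg)
    sim <- simulate_genotypes(sea$sites, sea$env, cfg)
    site <- attr(sim$genotypes, "site")
    ad <- sim$truth[sim$truth$is_adaptive, ]
    rho <- vapply(seq_len(nrow(ad)), function(i) {
      z <- scale(sea$env[[ad$driving_variable[i]]])[match(site, sea$sites$site)]
      suppressWarnings(cor(sim$genotypes$dosage[, ad$locus_id[i]], z,
                           method = "spearman"))
    }, numeric(1))
    mean(abs(rho), na.rm = TRUE)
  })
  expect_true(all(diff(m_abs_rho) > 0))
})
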