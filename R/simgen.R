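#' Simulation configuration for a synthetic seascape study
#'
#' Bundles every knob of the synthetic data generator: the sampling design
#' (sites along a 1-D coast, individuals per site), the genotype panel
#' (neutral loci under isolation-by-distance drift, adaptive loci whose site
#' allele frequencies follow an environmental gradient), the environmental
#' table (named variables with smooth along-coast shapes, site-level noise,
#' and a target correlation structure), and nuisance processes (uniform
#' missingness).
#'
#' Defaults emulate a ddRAD-style coastal study: 9 sites, ~22 individuals
#' per site (200 in total), 2000 neutral + 50 adaptive biallelic SNPs, 1%
#' missing data, weak neutral differentiation (F_ST ~ 0.02), three
#' correlated environmental gradients, and an adaptive effect of 2 log-odds
#' per SD of the driving variable.
#'
#' @param n_sites number of sampling sites along the coast.
#' @param per_site_n individuals per site; scalar or length-`n_sites` vector.
#' @param n_neutral,n_adaptive locus counts.
#' @param env_vars named list; each element `list(shape=, noise_sd=)` with
#'   shape one of `"linear"`, `"sigmoid"`, `"bump"`, `"sine"`.
#' @param env_correlation optional target correlation matrix (vars x vars);
#'   realized site-level correlations approach it as noise_sd -> 0.
#' @param migration_rate kept for completeness of the stepping-stone
#'   narrative; differentiation is governed directly by `drift_fst`.
#' @param drift_fst target multilocus neutral Weir-Cockerham F_ST.
#' @param effect_size adaptive effect, log-odds per SD of driving variable.
#' @param missing_rate fraction of genotype calls set missing at random.
#' @param coord_jitter_sd SD (decimal degrees) of the scatter of individual
#'   sampling coordinates around their site centroid, emulating at-sea
#'   sampling; individual-level spatial eigenvectors need this within-site
#'   coordinate variation.
#' @param seed integer master seed; stage streams are derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 9,
                       per_site_n = NULL,
                       n_neutral = 2000,
                       n_adaptive = 50,
                       env_vars = list(
                         sst_min       = list(shape = "sigmoid", noise_sd = 0.15),
                         salinity_max  = list(shape = "sine",    noise_sd = 0.15),
                         prod_max      = list(shape = "bump",    noise_sd = 0.15)
                       ),
                       env_correlation = NULL,
                       migration_rate = 0.1,
                       drift_fst = 0.02,
                       effect_size = 2,
                       missing_rate = 0.01,
                       coord_jitter_sd = 0.1,
                       seed = 1L) {
  if (is.null(per_site_n)) {
    base <- rep(200L %/% n_sites, n_sites)
    extra <- 200L %% n_sites
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    per_site_n <- base
  }
  if (length(per_site_n) == 1) per_site_n <- rep(as.integer(per_site_n), n_sites)
  stopifnot(
    n_sites >= 1, length(per_site_n) == n_sites, all(per_site_n >= 1),
    n_neutral >= 0, n_adaptive >= 0, n_neutral + n_adaptive >= 1,
    migration_rate >= 0, migration_rate <= 1,
    missing_rate >= 0, missing_rate < 1,
    drift_fst > 0, drift_fst < 1
  )
  if (!is.null(env_correlation)) {
    V <- length(env_vars)
    stopifnot(is.matrix(env_correlation),
              nrow(env_correlation) == V, ncol(env_correlation) == V)
    ev <- eigen(env_correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("env_correlation must be positive semi-definite")
  }
  structure(list(
    n_sites = as.integer(n_sites), per_site_n = as.integer(per_site_n),
    n_neutral = as.integer(n_neutral), n_adaptive = as.integer(n_adaptive),
    env_vars = env_vars, env_correlation = env_correlation,
    migration_rate = migration_rate, drift_fst = drift_fst,
    effect_size = effect_size, missing_rate = missing_rate,
    coord_jitter_sd = coord_jitter_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Water mask constructor
#'
#' A rectangular raster of water (TRUE) / land (FALSE) cells in geographic
#' coordinates, stored ESRI-ASCII style: row 1 is the northernmost row,
#' `origin_lon`/`origin_lat` give the lower-left corner.
#'
#' @param grid logical matrix, TRUE = water.
#' @param origin_lon,origin_lat lower-left corner, decimal degrees.
#' @param cell_size cell edge in degrees.
#' @export
water_mask <- function(grid, origin_lon, origin_lat, cell_size) {
  stopifnot(is.matrix(grid), is.logical(grid), cell_size > 0, any(grid))
  structure(list(grid = grid, origin_lon = origin_lon,
                 origin_lat = origin_lat, cell_size = cell_size),
            class = "water_mask")
}

# centre coordinates of cell (i = row from north, j = col from west)
.mask_cell_center <- function(mask, i, j) {
  nr <- nrow(mask$grid)
  list(lon = mask$origin_lon + (j - 0.5) * mask$cell_size,
       lat = mask$origin_lat + (nr - i + 0.5) * mask$cell_size)
}

.shape_fun <- function(shape) {
  switch(shape,
    linear  = function(s) s,
    sigmoid = function(s) stats::plogis(10 * (s - 0.5)),
    bump    = function(s) exp(-(s - 0.5)^2 / (2 * 0.18^2)),
    sine    = function(s) sin(2 * pi * s),
    stop("unknown gradient shape: ", shape)
  )
}

# impose a target correlation matrix on standardized smooth columns while
# preserving the first column's shape; returns site x vars matrix
.correlate_columns <- function(E, C) {
  n <- nrow(E); V <- ncol(E)
  basis <- E
  # supplement with orthogonal polynomials if the shapes are collinear
  extra <- stats::poly(seq_len(n), degree = min(n - 1, V))
  Q <- qr.Q(qr(cbind(basis, extra)))[, seq_len(V), drop = FALSE]
  # align sign so the first basis vector keeps the first shape's direction
  for (k in seq_len(V)) {
    s <- sum(Q[, k] * basis[, min(k, ncol(basis))])
    if (s < 0) Q[, k] <- -Q[, k]
  }
  U <- suppressWarnings(chol(C, pivot = TRUE))
  U <- U[, order(attr(U, "pivot")), drop = FALSE]
  out <- Q %*% U * sqrt(n - 1)
  dimnames(out) <- dimnames(E)
  out
}

#' Generate the synthetic seascape: water mask, sites, environmental table
#'
#' Sites are placed evenly along a 1-D coastline (a land strip bounding a
#' water band); each environmental variable is a deterministic smooth
#' function of along-coast position plus independent Gaussian site noise.
#' When `config$env_correlation` is supplied, the noise-free site values
#' realize that correlation matrix exactly (the first variable keeps its
#' nominal shape; the others are smooth combinations of orthogonalized
#' shape bases).
#'
#' @param config a [sim_config()].
#' @param site_lon,site_lat optional explicit site coordinates (decimal
#'   degrees); any site falling on land is an error naming the site.
#' @return list with `mask` (a [water_mask()]), `sites` (data.frame:
#'   site, lon, lat, s = along-coast position in `[0,1]`) and `env`
#'   (data.frame: site + one column per variable).
#' @export
make_seascape <- function(config, site_lon = NULL, site_lat = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "seascape"))
  n <- config$n_sites
  ncols <- max(20L, 4L * n); nrows <- 12L
  cs <- 0.1
  grid <- matrix(TRUE, nrows, ncols)
  grid[1:2, ] <- FALSE                       # coastline strip along the north
  mask <- water_mask(grid, origin_lon = 130, origin_lat = -37, cell_size = cs)

  if (is.null(site_lon)) {
    j <- round(seq(2, ncols - 1, length.out = n))
    i <- rep(3L, n)                          # first water row under the coast
    cc <- .mask_cell_center(mask, i, j)
    site_lon <- cc$lon; site_lat <- cc$lat
  }
  site <- sprintf("S%02d", seq_len(n))
  ij <- .snap_to_water(mask, site_lon, site_lat, max_cells = 0)
  on_land <- is.na(ij$i)
  if (any(on_land)) {
    stop("site(s) on land: ", paste(site[on_land], collapse = ", "))
  }
  s <- if (n == 1) 0 else (site_lon - min(site_lon)) / diff(range(site_lon))

  vars <- names(config$env_vars)
  E <- sapply(config$env_vars, function(v) .shape_fun(v$shape)(s))
  E <- matrix(E, nrow = n, dimnames = list(NULL, vars))
  # standardize the deterministic part across sites
  E <- apply(E, 2, function(x) {
    sdx <- stats::sd(x)
    if (sdx < 1e-12) stop("constant gradient over sites")
    (x - mean(x)) / sdx
  })
  E <- matrix(E, nrow = n, dimnames = list(NULL, vars))
  if (!is.null(config$env_correlation)) {
    E <- .correlate_columns(E, config$env_correlation)
  }
  for (k in seq_along(vars)) {
    nsd <- config$env_vars[[k]]$noise_sd
    if (nsd > 0) E[, k] <- E[, k] + stats::rnorm(n, 0, nsd)
  }
  list(mask = mask,
       sites = data.frame(site = site, lon = site_lon, lat = site_lat, s = s,
                          stringsAsFactors = FALSE),
       env = data.frame(site = site, E, stringsAsFactors = FALSE))
}

# ---- neutral stepping-stone frequencies -----------------------------------

# one chain of site frequencies: p[1] = ancestral, then beta-perturbed along
# the chain with concentration nu; u is an (n_sites-1) matrix of fixed
# uniforms so that bisection over nu is smooth
.chain_freqs <- function(p0, nu, u) {
  n_loci <- length(p0); n_sites <- nrow(u) + 1
  P <- matrix(NA_real_, n_sites, n_loci)
  P[1, ] <- p0
  for (s in 2:n_sites) {
    p <- pmin(pmax(P[s - 1, ], 1e-3), 1 - 1e-3)
    P[s, ] <- stats::qbeta(u[s - 1, ], nu * p, nu * (1 - p))
  }
  pmin(pmax(P, 0.01), 0.99)
}

# population-level theta of a site-frequency matrix (large-sample limit of
# Weir-Cockerham, ratio of sums over loci)
.freq_theta <- function(P) {
  r <- nrow(P)
  pbar <- colMeans(P)
  s2 <- apply(P, 2, stats::var)              # among-site variance, n-1 denom
  num <- s2
  den <- pbar * (1 - pbar) + s2 / r
  sum(num) / sum(den)
}

# calibrate the beta concentration so realized neutral theta ~ drift_fst
.calibrate_nu <- function(config) {
  set.seed(derive_seed(config$seed, "calibrate"))
  n_cal <- 400L
  p0 <- stats::runif(n_cal, 0.1, 0.9)
  u <- matrix(stats::runif((config$n_sites - 1) * n_cal),
              nrow = config$n_sites - 1)
  f <- function(log_nu) .freq_theta(.chain_freqs(p0, exp(log_nu), u)) - config$drift_fst
  lo <- log(2); hi <- log(5e4)
  if (f(lo) < 0) return(exp(lo))
  if (f(hi) > 0) return(exp(hi))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root)
}

#' Simulate genotypes over the seascape with a planted truth set
#'
#' Neutral loci: site allele frequencies follow a discretized 1-D
#' stepping-stone diffusion (beta-perturbed along the site chain) whose
#' concentration is pre-calibrated by root finding so that the realized
#' multilocus Weir-Cockerham F_ST approximates `config$drift_fst`.
#' Adaptive loci: site frequency `plogis(a + b * z_s)` with `z_s` the
#' standardized driving variable (assigned round-robin over environmental
#' variables) and `b = config$effect_size`. Individual genotypes are
#' Binomial(2, p_site); missingness is uniform at random.
#'
#' @param sites,env as returned by [make_seascape()].
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (data.frame: locus_id, is_adaptive, driving_variable, effect_size).
#' @export
simulate_genotypes <- function(sites, env, config) {
  stopifnot(inherits(config, "sim_config"))
  vars <- setdiff(names(env), "site")
  if (config$n_adaptive > 0 && length(vars) == 0) {
    stop("adaptive loci requested but no environmental variables supplied")
  }
  nu <- if (config$n_neutral > 0) .calibrate_nu(config) else NA_real_
  set.seed(derive_seed(config$seed, "genotypes"))
  n_sites <- nrow(sites)
  n_ind <- sum(config$per_site_n)
  L <- config$n_neutral + config$n_adaptive

  # site frequency matrix (sites x loci)
  P <- matrix(NA_real_, n_sites, L)
  if (config$n_neutral > 0) {
    p0 <- stats::runif(config$n_neutral, 0.1, 0.9)
    u <- matrix(stats::runif((n_sites - 1) * config$n_neutral),
                nrow = max(n_sites - 1, 1))
    P[, seq_len(config$n_neutral)] <- .chain_freqs(p0, nu, u)
  }
  driving <- rep(NA_character_, L)
  if (config$n_adaptive > 0) {
    Z <- scale(as.matrix(env[, vars, drop = FALSE]))
    for (k in seq_len(config$n_adaptive)) {
      v <- vars[((k - 1) %% length(vars)) + 1]
      j <- config$n_neutral + k
      driving[j] <- v
      a <- stats::qlogis(stats::runif(1, 0.3, 0.7))
      P[, j] <- stats::plogis(a + config$effect_size * Z[, v])
    }
  }

  site_of <- rep(seq_len(n_sites), config$per_site_n)
  G <- matrix(NA_integer_, n_ind, L)
  for (s in seq_len(n_sites)) {
    rows <- which(site_of == s)
    G[rows, ] <- matrix(
      stats::rbinom(length(rows) * L, 2, rep(P[s, ], each = length(rows))),
      nrow = length(rows))
  }
  if (config$missing_rate > 0) {
    G[stats::runif(length(G)) < config$missing_rate] <- NA_integer_
  }

  locus_id <- sprintf("snp_%05d", seq_len(L))
  # flip to globally-minor coding; remember which allele is counted
  flip <- logical(L)
  for (j in seq_len(L)) {
    obs <- G[, j]
    tot <- sum(!is.na(obs))
    if (tot > 0 && sum(obs, na.rm = TRUE) > tot) {  # alt freq > 0.5
      G[, j] <- 2L - G[, j]
      flip[j] <- TRUE
    }
  }
  n_contig <- 5L
  contig <- sprintf("chr%d", ((seq_len(L) - 1) %% n_contig) + 1)
  pos <- 1000L * (((seq_len(L) - 1) %/% n_contig) + 1L)
  ref <- ifelse(flip, "G", "A")
  alt <- ifelse(flip, "A", "G")

  sample_id <- sprintf("%s_i%02d", sites$site[site_of],
                       unlist(lapply(config$per_site_n, seq_len)))
  gm <- genotype_matrix(G, sample_id, locus_id,
                        loci = data.frame(locus_id = locus_id, contig = contig,
                                          pos = pos, ref = ref, alt = alt,
                                          stringsAsFactors = FALSE),
                        site = sites$site[site_of])
  truth <- data.frame(
    locus_id = locus_id,
    is_adaptive = seq_len(L) > config$n_neutral,
    driving_variable = ifelse(is.na(driving), "none", driving),
    effect_size = ifelse(is.na(driving), 0, config$effect_size),
    stringsAsFactors = FALSE)
  list(genotypes = gm, truth = truth)
}

#' Append planted duplicate individuals
#'
#' Copies `n_pairs` randomly chosen individuals, re-applies missingness
#' independently, and appends them with `_dup` ids; used to exercise the
#' relatedness screen.
#'
#' @param G a [genotype_matrix()].
#' @param n_pairs number of duplicates to plant.
#' @param seed integer seed.
#' @param missing_rate extra uniform missingness applied to the copies.
#' @return a [genotype_matrix()] with `attr(,"planted_pairs")` listing
#'   (source, duplicate) id pairs.
#' @export
plant_relatives <- function(G, n_pairs, seed = 1L, missing_rate = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"), n_pairs >= 0,
            n_pairs <= nrow(G$dosage))
  if (n_pairs == 0) {
    attr(G, "planted_pairs") <- data.frame(source = character(),
                                           duplicate = character())
    return(G)
  }
  set.seed(derive_seed(seed, "relatives"))
  src <- sample.int(nrow(G$dosage), n_pairs)
  dup <- G$dosage[src, , drop = FALSE]
  if (missing_rate > 0) {
    dup[stats::runif(length(dup)) < missing_rate] <- NA_integer_
  }
  dup_ids <- sprintf("%s_dup%d", G$sample_ids[src], seq_len(n_pairs))
  site <- attr(G, "site")
  D <- rbind(G$dosage, dup)
  loci <- G$loci
  # appending copies can tip a locus across 0.5; restore minor coding
  for (j in seq_len(ncol(D))) {
    obs <- D[, j]
    if (sum(obs, na.rm = TRUE) > sum(!is.na(obs))) {
      D[, j] <- 2L - D[, j]
      tmp <- loci$ref[j]; loci$ref[j] <- loci$alt[j]; loci$alt[j] <- tmp
    }
  }
  out <- genotype_matrix(D, c(G$sample_ids, dup_ids), G$locus_ids, loci,
                         site = if (!is.null(site)) c(site, site[src]))
  attr(out, "planted_pairs") <- data.frame(source = G$sample_ids[src],
                                           duplicate = dup_ids,
                                           stringsAsFactors = FALSE)
  out
}

#' Simulate a complete study fixture
#'
#' Convenience wrapper: seascape, genotypes, per-individual sampling
#' coordinates (site centroid plus seaward jitter), truth table and planted
#' duplicates from one configuration.
#'
#' @param config a [sim_config()].
#' @param n_dup_pairs planted duplicate pairs (default 2).
#' @return list: `config`, `mask`, `sites`, `env`, `genotypes`, `samples`
#'   (per-individual sample_id, site, lon, lat), `truth`, `planted_pairs`.
#' @export
simulate_study <- function(config = sim_config(), n_dup_pairs = 2) {
  sea <- make_seascape(config)
  sim <- simulate_genotypes(sea$sites, sea$env, config)
  G <- plant_relatives(sim$genotypes, n_dup_pairs, seed = config$seed,
                       missing_rate = config$missing_rate)
  samples <- .jitter_coords(G, sea, config)
  list(config = config, mask = sea$mask, sites = sea$sites, env = sea$env,
       genotypes = G, samples = samples, truth = sim$truth,
       planted_pairs = attr(G, "planted_pairs"))
}

# per-individual coordinates: site centroid plus seaward scatter, kept
# inside the water band of the mask
.jitter_coords <- function(G, sea, config) {
  set.seed(derive_seed(config$seed, "coords"))
  site <- attr(G, "site")
  idx <- match(site, sea$sites$site)
  jit <- config$coord_jitter_sd %||% 0
  n <- length(site)
  lon <- sea$sites$lon[idx] + stats::rnorm(n, 0, jit)
  lat <- sea$sites$lat[idx] - abs(stats::rnorm(n, 0, jit))
  m <- sea$mask
  lon_rng <- m$origin_lon + c(0.5, ncol(m$grid) - 0.5) * m$cell_size
  lat_min <- m$origin_lat + 0.5 * m$cell_size
  lon <- pmin(pmax(lon, lon_rng[1]), lon_rng[2])
  lat <- pmin(pmax(lat, lat_min), sea$sites$lat[idx])
  data.frame(sample_id = G$sample_ids, site = site, lon = lon, lat = lat,
             stringsAsFactors = FALSE)
}
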