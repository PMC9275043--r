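# Oceanic least-cost distances on a rasterized water mask and dbMEM
# spatial eigenvectors.

open_mask <- function(nr = 12, nc = 30, cs = 0.1, lat0 = -37, lon0 = 130) {
  water_mask(matrix(TRUE, nr, nc), lon0, lat0, cs)
}

test_that("open-water distances approach great-circle distances", {
  mask <- open_mask()
  # straight corridor along the grid: discretization error well inside the
  # 8% octile bound
  p1 <- data.frame(site = c("a", "b"),
                   lon = c(130.15, 132.85), lat = c(-36.55, -36.55))
  D1 <- oceanic_distances(p1, mask)
  gc1 <- geosphere::distHaversine(c(130.15, -36.55), c(132.85, -36.55)) / 1000
  expect_lt(abs(D1["a", "b"] - gc1) / gc1, 0.08)

  # halving the cell size shrinks the snapping error toward great circle
  # (points sit off the coarse centres but on fine-grid cell centres)
  p2 <- data.frame(site = c("a", "b"),
                   lon = c(130.175, 132.825), lat = c(-36.575, -36.575))
  gc2 <- geosphere::distHaversine(c(130.175, -36.575),
                                  c(132.825, -36.575)) / 1000
  Dc <- oceanic_distances(p2, mask)
  fine <- open_mask(nr = 24, nc = 60, cs = 0.05)
  Df <- oceanic_distances(p2, fine)
  expect_lt(abs(Df["a", "b"] - gc2) / gc2, 0.08)
  expect_lt(abs(Df["a", "b"] - gc2), abs(Dc["a", "b"] - gc2))
})

test_that("a peninsula forces the hand-verified detour", {
  g <- matrix(TRUE, 10, 10)
  g[1:7, 5] <- FALSE                  # wall from the top, gap in rows 8-10
  mask <- water_mask(g, 0, 0, 0.1)
  pts <- data.frame(site = c("w", "e"),
                    lon = c(0.25, 0.65), lat = c(0.85, 0.85))  # row 2, cols 3/7
  D <- oceanic_distances(pts, mask)
  # independent oracle: Bellman-Ford relaxation on the same water grid
  nodes <- which(g)
  coord <- arrayInd(nodes, dim(g))
  lon <- 0 + (coord[, 2] - 0.5) * 0.1
  lat <- 0 + (10 - coord[, 1] + 0.5) * 0.1
  n <- length(nodes)
  W <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && abs(coord[i, 1] - coord[j, 1]) <= 1 &&
        abs(coord[i, 2] - coord[j, 2]) <= 1) {
      W[i, j] <- geosphere::distHaversine(c(lon[i], lat[i]),
                                          c(lon[j], lat[j])) / 1000
    }
  }
  src <- which(coord[, 1] == 2 & coord[, 2] == 3)
  dst <- which(coord[, 1] == 2 & coord[, 2] == 7)
  dist <- rep(Inf, n); dist[src] <- 0
  for (it in seq_len(n)) {
    new <- pmin(dist, apply(W + dist, 2, min))
    if (all(new == dist)) break
    dist <- new
  }
  expect_equal(D["w", "e"], dist[dst], tolerance = 1e-9)
  # and the detour is materially longer than the blocked straight line
  expect_gt(D["w", "e"],
            geosphere::distHaversine(c(0.25, 0.85), c(0.65, 0.85)) / 1000 * 1.5)
})

test_that("distances are symmetric and respect input order", {
  mask <- open_mask()
  pts <- data.frame(site = c("a", "b", "c"),
                    lon = c(130.3, 131.1, 132.2), lat = c(-36.6, -36.4, -36.7))
  D <- oceanic_distances(pts, mask)
  Dp <- oceanic_distances(pts[c(3, 1, 2), ], mask)
  expect_equal(D, t(D))
  expect_equal(Dp[c("a", "b", "c"), c("a", "b", "c")], D)
})

test_that("unsnappable points name the offending sample", {
  g <- matrix(TRUE, 10, 10); g[1:5, ] <- FALSE
  mask <- water_mask(g, 0, 0, 0.1)
  pts <- data.frame(site = c("ok", "landlocked"),
                    lon = c(0.5, 0.5), lat = c(0.2, 0.95))
  expect_error(oceanic_distances(pts, mask, snap_cells = 1), "landlocked")
})

test_that("dbMEM eigenvectors are centred, orthonormal, and match a dense oracle", {
  # 4 equidistant collinear points
  D <- as.matrix(dist(cbind(c(0, 1, 2, 3), 0))) * 100
  basis <- build_dbmem(D, positive_only = FALSE)
  V <- basis$vectors
  expect_lt(max(abs(colSums(V))), 1e-8)
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # oracle: rebuild the centred Gower matrix explicitly and eigendecompose
  tr <- basis$truncation
  Ds <- D; Ds[Ds > tr] <- 4 * tr; diag(Ds) <- 0
  A <- -0.5 * Ds^2
  n <- nrow(D)
  H <- diag(n) - 1 / n
  ev <- eigen(H %*% A %*% H, symmetric = TRUE)
  oracle <- ev$values[abs(ev$values) > 1e-8 * max(abs(ev$values))]
  expect_equal(basis$eigenvalues, oracle, tolerance = 1e-8)
})

test_that("the leading eigenvector is the broadest-scale pattern", {
  coords <- cbind(seq(0, 800, length.out = 9), 0)
  D <- as.matrix(dist(coords))
  basis <- build_dbmem(D)
  sign_changes <- apply(basis$vectors, 2, function(v) sum(diff(sign(v)) != 0))
  expect_equal(unname(which.min(sign_changes)), 1L)
  expect_true(all(sign_changes[1] <= sign_changes))
})

test_that("eigenvalue order matches Moran's I under the truncated weighting", {
  set.seed(4)
  coords <- cbind(cumsum(runif(12, 30, 80)), runif(12, -5, 5))
  D <- as.matrix(dist(coords))
  basis <- build_dbmem(D, positive_only = FALSE)
  tr <- basis$truncation
  # the Gower-centred -d^2/2 construction is an MEM with neighbour weights
  # (16 t^2 - d^2)/2; Moran's I under those weights must sort identically
  W <- 0.5 * (16 * tr^2 - D^2) * (D <= tr)
  diag(W) <- 0
  I <- apply(basis$vectors, 2, morans_i, W = W)
  expect_equal(cor(I, basis$eigenvalues, method = "spearman"), 1)
})

test_that("forward MEM selection finds a planted broad-scale shift first", {
  set.seed(21)
  coords <- cbind(seq(0, 800, length.out = 9), 0)
  D <- as.matrix(dist(coords))
  basis <- build_dbmem(D)
  site <- rep(seq_len(9), each = 12)
  mems <- basis$vectors[site, , drop = FALSE]
  Y <- matrix(rnorm(108 * 80), 108, 80)
  Y <- Y + outer(mems[, 1], rnorm(80, 0, 1.2))   # site-mean shift along MEM1
  sel <- forward_select_mems(Y, mems, n_perm = 99, seed = 2)
  expect_equal(sel$selected[1], 1L)

  expect_length(forward_select_mems(Y, mems, alpha = 0, n_perm = 99,
                                    seed = 2)$selected, 0)
})
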