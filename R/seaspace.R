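# Least-cost over-water distances on a rasterized seascape, and
# distance-based Moran's eigenvector maps (dbMEM) as spatial covariates.

# map lon/lat points to water cells: returns list(i, j) row/col indices,
# NA where the point cannot be snapped within max_cells of its own cell
.snap_to_water <- function(mask, lon, lat, max_cells = 2) {
  g <- mask$grid; nr <- nrow(g); nc <- ncol(g); cs <- mask$cell_size
  j0 <- floor((lon - mask$origin_lon) / cs) + 1
  i0 <- nr - floor((lat - mask$origin_lat) / cs)
  i_out <- rep(NA_integer_, length(lon)); j_out <- rep(NA_integer_, length(lon))
  for (k in seq_along(lon)) {
    best <- NULL; best_d <- Inf
    for (di in -max_cells:max_cells) {
      for (dj in -max_cells:max_cells) {
        i <- i0[k] + di; j <- j0[k] + dj
        if (i < 1 || i > nr || j < 1 || j > nc || !g[i, j]) next
        cc <- .mask_cell_center(mask, i, j)
        d <- geosphere::distHaversine(c(lon[k], lat[k]), c(cc$lon, cc$lat))
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (!is.null(best)) { i_out[k] <- best[1]; j_out[k] <- best[2] }
  }
  list(i = i_out, j = j_out)
}

# graph over water cells, 8-connected, edge weights great-circle km
.water_graph <- function(mask) {
  g <- mask$grid; nr <- nrow(g); nc <- ncol(g)
  id <- matrix(NA_integer_, nr, nc)
  wc <- which(g)
  id[wc] <- seq_along(wc)
  coord <- arrayInd(wc, dim(g))
  cc <- .mask_cell_center(mask, coord[, 1], coord[, 2])
  centers <- cbind(cc$lon, cc$lat)
  edges <- list(); w <- list()
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (s in shifts) {
    i1 <- coord[, 1] + s[1]; j1 <- coord[, 2] + s[2]
    ok <- i1 >= 1 & i1 <= nr & j1 >= 1 & j1 <= nc
    ok[ok] <- g[cbind(i1[ok], j1[ok])]
    if (!any(ok)) next
    from <- id[wc[ok]]
    to <- id[cbind(i1[ok], j1[ok])]
    d <- geosphere::distHaversine(centers[from, , drop = FALSE],
                                  centers[to, , drop = FALSE]) / 1000
    edges[[length(edges) + 1]] <- rbind(from, to)
    w[[length(w) + 1]] <- d
  }
  graph <- igraph::make_graph(as.vector(do.call(cbind, edges)),
                              n = length(wc), directed = FALSE)
  igraph::E(graph)$weight <- unlist(w)
  list(graph = graph, id = id, centers = centers)
}

#' Least-cost oceanic distances between sampling points
#'
#' Each point is snapped to the nearest water cell (within `snap_cells`
#' cells); distances are shortest paths over the 8-connected water-cell
#' graph with great-circle edge lengths, in kilometres.
#'
#' @param coords data.frame with `lon`, `lat` and optionally a name column
#'   (first non-coordinate column used for labels).
#' @param mask a [water_mask()].
#' @param snap_cells snap radius in cells.
#' @return symmetric matrix of distances in km.
#' @export
oceanic_distances <- function(coords, mask, snap_cells = 2) {
  labels <- if ("site" %in% names(coords)) coords$site
            else if ("sample_id" %in% names(coords)) coords$sample_id
            else sprintf("p%d", seq_len(nrow(coords)))
  sn <- .snap_to_water(mask, coords$lon, coords$lat, max_cells = snap_cells)
  if (anyNA(sn$i)) {
    stop("cannot snap to water: ", paste(labels[is.na(sn$i)], collapse = ", "))
  }
  wg <- .water_graph(mask)
  v <- wg$id[cbind(sn$i, sn$j)]
  uv <- unique(v)
  Du <- igraph::distances(wg$graph, v = uv, to = uv)
  D <- Du[match(v, uv), match(v, uv), drop = FALSE]
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1, ]
    stop(sprintf("no over-water path between %s and %s",
                 labels[bad[1]], labels[bad[2]]))
  }
  dimnames(D) <- list(labels, labels)
  diag(D) <- 0
  D
}

#' Distance-based Moran's eigenvector maps
#'
#' Classical dbMEM: the distance matrix is truncated at `truncation` (auto =
#' the longest minimum-spanning-tree edge, which guarantees connectivity),
#' beyond-threshold entries are replaced by four times the threshold, the
#' matrix `-0.5 * d^2` is double-centred and eigendecomposed. Eigenvectors
#' with eigenvalues above numerical zero are returned, unit-norm, ordered by
#' descending eigenvalue (broad- to fine-scale spatial patterns; eigenvalues
#' are monotone in the Moran's I of their eigenvectors under the truncated
#' weighting).
#'
#' @param D symmetric distance matrix (km).
#' @param truncation threshold in km, or `"auto"`.
#' @param positive_only keep only positive-eigenvalue vectors (positive
#'   spatial autocorrelation), the default for downstream selection.
#' @param tol relative eigenvalue tolerance for "numerical zero".
#' @return object of class `mem_basis`: `vectors` (n x k), `eigenvalues`
#'   (descending), `truncation`.
#' @export
build_dbmem <- function(D, truncation = "auto", positive_only = TRUE,
                        tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 points for dbMEM")
  stopifnot(isSymmetric(unname(D), tol = 1e-6))
  D <- (D + t(D)) / 2                      # exact symmetry for the MST
  if (identical(truncation, "auto")) {
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(g)
    truncation <- max(igraph::E(mst)$weight)
  }
  tr <- truncation
  Ds <- D
  Ds[Ds > tr] <- 4 * tr
  diag(Ds) <- 0
  A <- -0.5 * Ds^2
  H <- diag(n) - matrix(1 / n, n, n)
  B <- H %*% A %*% H
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  thr <- tol * max(abs(e$values))
  keep <- if (positive_only) e$values > thr else abs(e$values) > thr
  V <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude element positive
  for (k in seq_len(ncol(V))) {
    m <- which.max(abs(V[, k]))
    if (V[m, k] < 0) V[, k] <- -V[, k]
  }
  colnames(V) <- sprintf("MEM%d", seq_len(ncol(V)))
  structure(list(vectors = V, eigenvalues = e$values[keep], truncation = tr),
            class = "mem_basis")
}

#' Moran's I spatial autocorrelation of a vector
#'
#' @param x numeric vector.
#' @param W weight matrix (zero diagonal).
#' @return Moran's I.
#' @export
morans_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  (n / sum(W)) * drop(z %*% W %*% z) / sum(z^2)
}

#' Expand site-level spatial eigenvectors to individuals
#'
#' @param basis a `mem_basis` built on site centroids (rows in the order of
#'   `site_levels`).
#' @param site per-individual site labels.
#' @param site_levels site order corresponding to the basis rows.
#' @return individuals x MEM matrix.
#' @export
expand_mem <- function(basis, site, site_levels) {
  idx <- match(site, site_levels)
  if (anyNA(idx)) stop("unknown site label(s): ",
                       paste(unique(site[is.na(idx)]), collapse = ", "))
  basis$vectors[idx, , drop = FALSE]
}

#' Forward-select spatial eigenvectors against the genotype response
#'
#' Applies [forward_select()] with the MEMs (already expanded to
#' individuals) as candidates and the mean-imputed centred genotype matrix
#' as response. When the purpose of the selected MEMs is to condition a
#' genotype-environment association, pass the standardized candidate
#' environmental table as `Z`: the spatial control then represents spatial
#' structure *not* attributable to the measured gradients, so that
#' spatially structured selection signal is not absorbed by the
#' conditioning set.
#'
#' @param G a [genotype_matrix()] (or an already-imputed numeric matrix).
#' @param mems individuals x MEM matrix (see [expand_mem()]).
#' @param alpha significance level (study default 0.05).
#' @param n_perm permutations (study default 100).
#' @param Z optional conditioning matrix (e.g., the standardized candidate
#'   environmental variables).
#' @param seed integer seed.
#' @param ... passed to [forward_select()].
#' @return list as [forward_select()].
#' @export
forward_select_mems <- function(G, mems, alpha = 0.05, n_perm = 100,
                                Z = NULL, seed = 1L, ...) {
  Y <- if (inherits(G, "genotype_matrix")) impute_dosage(G) else as.matrix(G)
  forward_select(Y, mems, Z = Z, alpha = alpha, n_perm = n_perm,
                 seed = seed, ...)
}
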