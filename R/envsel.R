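# Environmental-variable preparation: z-score standardization, reduction by
# pairwise correlation and variance inflation, and forward selection against
# the genotype response.

#' Standardize environmental variables to column z-scores
#'
#' Sample-SD (n-1) z-scores; a zero-variance column is an error naming the
#' variable.
#'
#' @param E data.frame or matrix (rows = individuals or sites).
#' @return matrix of the same shape with standardized columns.
#' @export
standardize_env <- function(E) {
  E <- as.matrix(E)
  if (!is.numeric(E) || any(!is.finite(E))) {
    stop("environmental table must be numeric and finite")
  }
  sds <- apply(E, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("zero-variance variable(s): ",
         paste(colnames(E)[sds < 1e-12], collapse = ", "))
  }
  scale(E)[, , drop = FALSE]
}

# variance inflation factors via the regression definition 1 / (1 - R^2_j)
.vif <- function(E) {
  V <- ncol(E)
  if (V < 2) return(stats::setNames(rep(1, V), colnames(E)))
  vif <- numeric(V)
  for (j in seq_len(V)) {
    y <- E[, j]
    X <- cbind(1, E[, -j, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    vif[j] <- 1 / max(1 - r2, 1e-300)
  }
  stats::setNames(vif, colnames(E))
}

#' Reduce collinearity by pairwise correlation then VIF
#'
#' Stage 1: while any pair has `|r| > r_max`, the worst pair is found and
#' the member with the larger mean absolute correlation to all other
#' remaining variables is dropped (ties: the later column). Stage 2: while
#' any variance inflation factor is at least `vif_max`, the variable with
#' the largest VIF is dropped. The full drop sequence with statistics is
#' attached as `attr(,"drops")`.
#'
#' @param E standardized environmental matrix with column names.
#' @param r_max pairwise correlation cap (study default 0.7).
#' @param vif_max VIF cap (study default 3).
#' @return character vector of kept variable names.
#' @export
collinearity_prune <- function(E, r_max = 0.7, vif_max = 3) {
  E <- as.matrix(E)
  if (is.null(colnames(E))) colnames(E) <- paste0("v", seq_len(ncol(E)))
  keep <- colnames(E)
  drops <- list()
  if (length(keep) < 2) {
    out <- keep
    attr(out, "drops") <- data.frame()
    return(out)
  }
  repeat {
    R <- stats::cor(E[, keep, drop = FALSE])
    absR <- abs(R); diag(absR) <- 0
    if (max(absR) <= r_max) break
    worst <- which(absR == max(absR), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- rowMeans(absR[pair, , drop = FALSE]) * length(keep) /
      max(length(keep) - 1, 1)
    drop_var <- if (abs(diff(mean_abs)) < 1e-12) {
      pair[which.max(match(pair, colnames(E)))]
    } else pair[which.max(mean_abs)]
    drops[[length(drops) + 1]] <- data.frame(
      stage = "correlation", variable = drop_var,
      statistic = max(absR), stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop_var)
    if (length(keep) < 2) break
  }
  repeat {
    if (length(keep) < 2) break
    vif <- .vif(E[, keep, drop = FALSE])
    if (max(vif) < vif_max) break
    drop_var <- names(vif)[which.max(vif)]
    drops[[length(drops) + 1]] <- data.frame(
      stage = "vif", variable = drop_var, statistic = max(vif),
      stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop_var)
  }
  attr(keep, "drops") <- if (length(drops)) do.call(rbind, drops)
                         else data.frame()
  keep
}

#' Forward-select environmental variables against the genotype response
#'
#' Same engine as [forward_select_mems()], with environmental columns as
#' candidates; the study retained variables explaining a significant
#' (p < 0.05) portion of genomic variation.
#'
#' @param G a [genotype_matrix()] (or an imputed numeric matrix).
#' @param E standardized (and pruned) environmental matrix, rows aligned to
#'   individuals.
#' @param Z optional conditioning matrix (e.g., selected MEMs).
#' @param alpha significance level.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param ... passed to [forward_select()].
#' @return list as [forward_select()]; `retained` gives variable names.
#' @export
forward_select_env <- function(G, E, Z = NULL, alpha = 0.05, n_perm = 1000,
                               seed = 1L, ...) {
  Y <- if (inherits(G, "genotype_matrix")) impute_dosage(G) else as.matrix(G)
  fs <- forward_select(Y, as.matrix(E), Z = Z, alpha = alpha,
                       n_perm = n_perm, seed = seed, ...)
  fs$retained <- colnames(as.matrix(E))[fs$selected]
  fs
}
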