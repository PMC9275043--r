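# Forward selection of predictors for a multivariate (genotype) response,
# with the double stopping rule: a global permutation pre-test of the full
# candidate model, then at each step the best remaining candidate is added
# only if (i) its partial effect is significant under permutation of the
# residuals of the current reduced model and (ii) the cumulative adjusted
# R^2 does not exceed that of the global model.

# squared-projection row sums for a stack of permuted basis matrices:
# returns, for each permutation, sum over response columns of the squared
# projections ||Q[perm]' Y||^2 split by the column blocks of Q
.perm_proj_ss <- function(Q, Y, perms, chunk = 200L) {
  n <- nrow(Y); q <- ncol(Q); B <- length(perms)
  out <- matrix(NA_real_, B, q)
  b0 <- 1L
  while (b0 <= B) {
    b1 <- min(b0 + chunk - 1L, B)
    idx <- b0:b1
    # invert each permutation so that Q'Y[perm,] == (Q[inv,])'Y
    stacked <- matrix(0, n, length(idx) * q)
    for (k in seq_along(idx)) {
      inv <- integer(n); inv[perms[[idx[k]]]] <- seq_len(n)
      stacked[, ((k - 1) * q + 1):(k * q)] <- Q[inv, , drop = FALSE]
    }
    cp <- crossprod(stacked, Y)          # (chunk*q) x L
    ss <- rowSums(cp^2)
    out[idx, ] <- matrix(ss, ncol = q, byrow = TRUE)
    b0 <- b1 + 1L
  }
  out
}

.adj_r2 <- function(r2, n_eff, q) {
  if (n_eff - q - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n_eff - 1) / (n_eff - q - 1)
}

#' Forward selection of predictors against a multivariate response
#'
#' The workhorse behind MEM and environmental-variable selection. The
#' response is centred (and residualized on conditioners `Z` if given);
#' candidates are added one at a time by largest additional explained
#' variance, each addition gated by a permutation p-value (residuals of the
#' current reduced model permuted, `p = (exceedances + 1) / (n_perm + 1)`)
#' and by the global adjusted-R^2 ceiling. A global permutation pre-test of
#' the all-candidate model guards the procedure's type-I error.
#'
#' @param Y numeric response matrix (individuals x loci).
#' @param X numeric candidate matrix (individuals x candidates).
#' @param Z optional conditioning matrix.
#' @param alpha per-step significance level.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param global_test run the global pre-test (recommended).
#' @param adjr2_stop enforce the global adjusted-R^2 ceiling.
#' @param step_null `"single"` (default, classical): the permutation null
#'   for a step is the chosen candidate's own gain distribution; paired
#'   with the global pre-test this holds the selection-frequency type-I
#'   error at the nominal level. `"max"` instead uses the distribution of
#'   the *largest* gain over all remaining candidates (correcting the
#'   pick-the-best selection bias per step, at the cost of a conservative
#'   overall procedure).
#' @return list: `selected` (column indices of `X` in selection order),
#'   `steps` (per-step statistics), `global_p`, `global_adj_r2`.
#' @export
forward_select <- function(Y, X, Z = NULL, alpha = 0.05, n_perm = 100,
                           seed = 1L, global_test = TRUE, adjr2_stop = TRUE,
                           step_null = c("single", "max")) {
  step_null <- match.arg(step_null)
  Y <- .center(as.matrix(Y)); X <- .center(as.matrix(X))
  n <- nrow(Y)
  stopifnot(nrow(X) == n, n_perm >= 1)
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  set.seed(derive_seed(seed, "forward"))
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)

  r <- 0L
  if (!is.null(Z) && ncol(as.matrix(Z)) > 0) {
    Qz <- .qr_basis(.center(as.matrix(Z)))
    r <- ncol(Qz)
    Y <- Y - Qz %*% crossprod(Qz, Y)
    X <- X - Qz %*% crossprod(Qz, X)
  }
  n_eff <- n - r
  tot <- sum(Y^2)
  if (tot < 1e-12) stop("response has no variance after conditioning")

  empty <- list(selected = integer(), steps = data.frame(),
                global_p = NA_real_, global_adj_r2 = NA_real_)

  Qall <- .qr_basis(X)
  qg <- ncol(Qall)
  if (qg == 0) return(empty)
  r2g <- sum(crossprod(Qall, Y)^2) / tot
  adj_g <- .adj_r2(r2g, n_eff, qg)
  pg <- NA_real_
  if (global_test) {
    f_obs <- (r2g / qg) / ((1 - r2g) / (n_eff - qg - 1))
    ss <- .perm_proj_ss(Qall, Y, perms)
    ssx <- rowSums(ss)
    f_b <- (ssx / qg) / ((tot - ssx) / (n_eff - qg - 1))
    pg <- (sum(f_b >= f_obs) + 1) / (n_perm + 1)
    if (pg > alpha) return(utils::modifyList(empty, list(global_p = pg,
                                                         global_adj_r2 = adj_g)))
  }

  selected <- integer()
  steps <- list()
  Qsel <- matrix(0, n, 0)
  E <- Y                                  # residuals of current reduced model
  remaining <- seq_len(ncol(X))
  ss_sel <- 0
  while (length(remaining) > 0) {
    gains <- rep(-Inf, length(remaining))
    qcand <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      xj <- X[, remaining[k]]
      if (ncol(Qsel) > 0) xj <- xj - Qsel %*% crossprod(Qsel, xj)
      nj <- sqrt(sum(xj^2))
      if (nj < 1e-8 * sqrt(n)) next
      qj <- xj / nj
      qcand[[k]] <- qj
      gains[k] <- sum(crossprod(qj, E)^2)
    }
    if (all(!is.finite(gains))) break
    k_best <- which.max(gains)
    gain_obs <- gains[k_best]
    qj <- qcand[[k_best]]
    if (step_null == "max") {
      live <- which(is.finite(gains))
      Qc <- do.call(cbind, qcand[live])
      ss <- .perm_proj_ss(Qc, E, perms)
      gain_b <- apply(ss, 1, max)
    } else {
      gain_b <- .perm_proj_ss(matrix(qj, ncol = 1), E, perms)[, 1]
    }
    p_step <- (sum(gain_b >= gain_obs) + 1) / (n_perm + 1)
    r2_new <- (ss_sel + gain_obs) / tot
    adj_new <- .adj_r2(r2_new, n_eff, length(selected) + 1L)
    if (p_step > alpha) break
    if (adjr2_stop && is.finite(adj_g) && adj_new > adj_g + 1e-8) break
    selected <- c(selected, remaining[k_best])
    steps[[length(steps) + 1]] <- data.frame(
      index = remaining[k_best], name = cn[remaining[k_best]],
      gain = gain_obs / tot, r2_cum = r2_new, adj_r2_cum = adj_new,
      p = p_step, stringsAsFactors = FALSE)
    Qsel <- cbind(Qsel, qj)
    ss_sel <- ss_sel + gain_obs
    E <- E - qj %*% crossprod(qj, E)
    remaining <- remaining[-k_best]
  }
  list(selected = selected,
       steps = if (length(steps)) do.call(rbind, steps) else data.frame(),
       global_p = pg, global_adj_r2 = adj_g)
}
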