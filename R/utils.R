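#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline each consume their own RNG stream so that a stage
#' can be re-run in isolation and reproduce its in-pipeline behaviour. The
#' derivation hashes the stage name into a 31-bit offset.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 1977326743  # 7^11, prime-ish modulus
  as.integer((abs(seed) + h) %% .Machine$integer.max)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# format doubles so that read-back reproduces the binary value exactly
.fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

# write a data.frame as CSV with round-trip-exact doubles
.write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

# centre the columns of a matrix
.center <- function(M) sweep(M, 2, colMeans(M), "-")

# orthonormal basis of the column space of X after removing the intercept
# (and optional conditioners already orthonormalized); returns n x q matrix,
# possibly with fewer columns than X if rank-deficient (tol on diagonal of R)
.qr_basis <- function(X, tol = 1e-9) {
  if (is.null(X) || ncol(X) == 0) return(matrix(0, nrow(X) %||% 0, 0))
  qx <- qr(X)
  r <- sum(abs(diag(qr.R(qx))) > tol * max(abs(diag(qr.R(qx))), 1))
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}
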