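# Internal helpers shared across modules.

#' Repair a symmetric matrix to the nearest positive semi-definite
#' correlation matrix
#'
#' Eigenvalues below `tol` are clipped to `tol`, the matrix is rebuilt and
#' rescaled to unit diagonal. Used by the synthetic community generator,
#' where user-specified edge plans are rarely exactly PSD.
#'
#' @param mat square symmetric numeric matrix with unit diagonal.
#' @param tol eigenvalue floor (default 1e-10).
#' @param quiet suppress the repair warning.
#' @return a positive semi-definite correlation matrix.
#' @keywords internal
nearest_psd <- function(mat, tol = 1e-10, quiet = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  mat <- (mat + t(mat)) / 2
  eig <- eigen(mat, symmetric = TRUE)
  if (min(eig$values) >= 0) {
    return(mat)
  }
  if (!quiet) {
    warning("latent correlation matrix is not PSD; clipping eigenvalues at ",
            format(tol), call. = FALSE)
  }
  vals <- pmax(eig$values, tol)
  out <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

# All permutations of seq_len(n) as an (n! x n) index matrix. Cached per n;
# n is capped at 8 (8! = 40,320 rows) — larger n uses the t-approximation
# upstream.
perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) {
    return(perm_cache[[key]])
  }
  perms <- matrix(1L, nrow = 1, ncol = 1)
  if (n > 1) {
    for (k in 2:n) {
      nr <- nrow(perms)
      out <- matrix(0L, nrow = nr * k, ncol = k)
      for (pos in seq_len(k)) {
        rows <- (pos - 1L) * nr + seq_len(nr)
        out[rows, pos] <- k
        out[rows, -pos] <- perms
      }
      perms <- out
    }
  }
  perm_cache[[key]] <- perms
  perms
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched, so generators are pure in (design, seed).
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
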