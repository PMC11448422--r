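# Spearman rank correlation over all taxon pairs with exact permutation
# p-values at small replicate numbers, and Benjamini-Hochberg FDR gating.
# The exact path matters because the study has n = 6 replicates per
# condition, where the usual t-approximation is at its worst.

# Average ranks (ties averaged), the ranking Spearman's rho is defined on.
avg_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rho with an exact permutation p-value
#'
#' Computes Spearman's rank correlation on average-ranked data and a
#' two-sided p-value: by full enumeration of all `n!` permutations of one
#' margin when `n <= exact_n` (ties handled exactly, since ranks are
#' permuted as-is), and by the t-approximation with `n - 2` degrees of
#' freedom otherwise.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact_n enumeration cutoff (default 8; 8! = 40,320 permutations).
#' @return list with elements `rho`, `p`, `method` ("exact" or "t-approx").
#' @examples
#' spearman_test(1:6, c(2, 4, 6, 8, 10, 12))  # rho 1, p = 2/720
#' @export
spearman_test <- function(x, y, exact_n = 8) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  }
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    # rho for every permutation is affine in sum(rx[perm] * ry)
    s <- matrix(rx[perms], nrow = nrow(perms)) %*% ry
    rho_all <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact")
  } else {
    list(rho = rho, p = spearman_t_p(rho, n), method = "t-approx")
  }
}

# Two-sided p from the t reference with n - 2 df (tie-corrected through the
# use of average ranks in rho itself).
spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' All-pairs Spearman correlation of taxon activity profiles
#'
#' Runs [spearman_test()] on every unordered pair of rows of a taxon-by-
#' replicate profile table and attaches BH-adjusted q-values over the whole
#' pair family. Constant (all-tied) taxa have no defined rank correlation
#' and are dropped with a warning before testing.
#'
#' @param profiles wide tibble: `taxon_id` plus one numeric column per
#'   replicate (counts or relative activities; Spearman only sees ranks).
#' @param exact_n enumeration cutoff passed to [spearman_test()].
#' @return tibble (taxon_i, taxon_j, rho, p, q, method), one row per pair.
#' @export
spearman_matrix <- function(profiles, exact_n = 8) {
  m <- count_matrix_numeric(profiles)
  if (ncol(m) < 3) stop("need >= 3 replicates", call. = FALSE)
  if (nrow(m) < 2) stop("need >= 2 taxa", call. = FALSE)
  constant <- apply(m, 1, function(r) length(unique(r)) == 1)
  if (any(constant)) {
    warning("dropping constant taxa before correlation: ",
            paste(rownames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[!constant, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 non-constant taxa", call. = FALSE)
  }
  pairs <- combn(rownames(m), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    st <- spearman_test(m[i, ], m[j, ], exact_n = exact_n)
    tibble(taxon_i = i, taxon_j = j, rho = st$rho, p = st$p,
           method = st$method)
  })
  res$q <- fdr_adjust(res$p)
  res[c("taxon_i", "taxon_j", "rho", "p", "q", "method")]
}

# like count_matrix() but allows fractional values (relative activity).
count_matrix_numeric <- function(profiles) {
  profiles <- as_tibble(profiles)
  stopifnot("taxon_id" %in% names(profiles))
  m <- as.matrix(profiles[setdiff(names(profiles), "taxon_id")])
  rownames(m) <- profiles$taxon_id
  storage.mode(m) <- "double"
  m
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min over j >= i of m * p_(j) / j`, clipped at
#' 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
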