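# Differential taxon activity between two conditions: median-of-ratios
# library-size normalization and a negative-binomial Wald test with
# method-of-moments dispersion. This is a deliberately simple, fully
# specified test in the DESeq2 mould — no trended-dispersion shrinkage, no
# fold-change shrinkage — because downstream use only needs the sign and the
# adjusted-significance call per taxon.

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference taxa of the ratio between the
#' sample's count and the taxon's geometric mean across samples. Reference
#' taxa are those with nonzero counts in every sample; if none exists, the
#' geometric means fall back to positive counts only, with a warning.
#'
#' @param counts activity table (wide tibble, `taxon_id` + sample columns).
#' @return named numeric vector of positive per-sample scaling factors.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  all_nonzero <- rowSums(m == 0) == 0
  if (any(all_nonzero)) {
    ref <- m[all_nonzero, , drop = FALSE]
    loggeo <- rowMeans(log(ref))
    # median of log ratios, so an even reference count averages
    # geometrically
    sf <- exp(apply(log(ref) - loggeo, 2, median))
  } else {
    warning("no taxon is nonzero in all samples; ",
            "using positive-count geometric means", call. = FALSE)
    geo <- apply(m, 1, function(r) {
      pos <- r[r > 0]
      if (length(pos) == 0) NA_real_ else exp(mean(log(pos)))
    })
    ratios <- m / geo
    sf <- apply(ratios, 2, function(col) median(col[col > 0], na.rm = TRUE))
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("size factors are not all positive", call. = FALSE)
  }
  sf
}

#' Negative-binomial Wald test of differential activity
#'
#' Per taxon, on size-factor-normalized counts: the log2 fold change of the
#' treatment mean over the reference mean (a pseudo-count of 0.5 is added on
#' both sides for the reported fold change only, so structural zeros do not
#' produce infinities); a pooled method-of-moments NB dispersion
#' `alpha = (var - mu) / mu^2` floored at 1e-8; a delta-method standard
#' error `SE(log2FC) = sqrt((1/mu_t + alpha)/n_t + (1/mu_r + alpha)/n_r) /
#' ln 2`; and a Wald statistic `z = log2FC_test / SE` referred to a t
#' distribution with `n_t + n_r - 2` degrees of freedom (the small-sample
#' calibration; at the study's 6-vs-6 scale a normal reference is visibly
#' anticonservative). p-values are BH-adjusted across tested taxa; taxa
#' all-zero in both conditions are skipped.
#'
#' @param counts activity table.
#' @param metadata sample metadata tibble (sample_id, condition).
#' @param reference,treatment condition labels to contrast.
#' @return object of class `differential_result`: tibble (taxon_id,
#'   base_mean, log2_fold_change, se, p, q, direction) with the contrast in
#'   attributes.
#' @export
test_differential <- function(counts, metadata, reference, treatment) {
  metadata <- as_tibble(metadata)
  for (cond in c(reference, treatment)) {
    if (!cond %in% metadata$condition) {
      stop("condition absent from metadata: ", cond, call. = FALSE)
    }
  }
  s_ref <- metadata$sample_id[metadata$condition == reference]
  s_trt <- metadata$sample_id[metadata$condition == treatment]
  if (length(s_ref) < 3 || length(s_trt) < 3) {
    stop("both conditions need >= 3 replicates", call. = FALSE)
  }
  m <- count_matrix(counts)[, c(s_ref, s_trt), drop = FALSE]
  sf <- size_factors(matrix_to_tibble(m))
  norm <- sweep(m, 2, sf, "/")
  ref <- norm[, s_ref, drop = FALSE]
  trt <- norm[, s_trt, drop = FALSE]
  n_r <- ncol(ref); n_t <- ncol(trt)
  mu_r <- rowMeans(ref); mu_t <- rowMeans(trt)
  tested <- mu_r + mu_t > 0
  # pooled within-group method-of-moments dispersion
  v_pool <- (apply(ref, 1, var) * (n_r - 1) +
               apply(trt, 1, var) * (n_t - 1)) / (n_r + n_t - 2)
  mu_pool <- (mu_r * n_r + mu_t * n_t) / (n_r + n_t)
  alpha <- pmax((v_pool - mu_pool) / mu_pool^2, 1e-8)
  lfc_disp <- log2((mu_t + 0.5) / (mu_r + 0.5))
  # test statistic uses the un-pseudocounted means where both are positive;
  # one-sided structural zeros fall back to the pseudo-counted contrast
  lfc_test <- ifelse(mu_r > 0 & mu_t > 0, log2(mu_t / mu_r), lfc_disp)
  se <- sqrt((1 / pmax(mu_t, 0.5) + alpha) / n_t +
               (1 / pmax(mu_r, 0.5) + alpha) / n_r) / log(2)
  z <- lfc_test / se
  p <- 2 * pt(-abs(z), df = n_r + n_t - 2)
  out <- tibble(taxon_id = rownames(m),
                base_mean = (mu_r + mu_t) / 2,
                log2_fold_change = lfc_disp,
                se = se, p = p)
  out <- out[tested, ]
  out$q <- fdr_adjust(out$p)
  out$direction <- sign(out$log2_fold_change)
  structure(out,
            class = c("differential_result", class(out)),
            reference = reference, treatment = treatment)
}

#' @rdname test_differential
#' @param x a `differential_result`.
#' @param ... unused.
#' @export
glance.differential_result <- function(x, ...) {
  tibble(reference = attr(x, "reference"),
         treatment = attr(x, "treatment"),
         n_tested = nrow(x),
         n_significant = sum(x$q < 0.05, na.rm = TRUE),
         n_up = sum(x$q < 0.05 & x$direction > 0, na.rm = TRUE),
         n_down = sum(x$q < 0.05 & x$direction < 0, na.rm = TRUE))
}

#' Fold-change strip plot of significant taxa
#'
#' Shows the log2 fold change of taxa with adjusted p below `alpha`:
#' negative values are taxa with decreased activity in the treatment
#' (curative) samples, positive values increased.
#'
#' @param object a `differential_result`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.differential_result <- function(object, alpha = 0.05, ...) {
  sig <- dplyr::filter(as_tibble(object), .data$q < alpha)
  ggplot2::ggplot(sig,
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = stats::reorder(.data$taxon_id,
                                                  .data$log2_fold_change),
                               colour = factor(.data$direction))) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c("-1" = "steelblue",
                                            "1" = "indianred"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (treatment / reference)", y = NULL) +
    ggplot2::theme_minimal()
}
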