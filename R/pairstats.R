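#' Pearson correlation with Fisher z transform
#'
#' Correlates two equal-length uniform series and reports Pearson's r, the
#' two-sided p-value, and Fisher's z (`atanh(r)`, with |r| capped at
#' 1 - 1e-12 so the transform stays finite). The p-value treats samples as
#' independent, as is conventional for these slow physiological series even
#' though they are serially correlated; an effective-sample-size-adjusted
#' p-value is available as an option.
#'
#' @param x,y Numeric vectors or (time, value) tibbles of equal length
#'   (n >= 3, finite, non-constant).
#' @param adjust_ess If `TRUE`, additionally report `p_ess`, the p-value
#'   with the sample size deflated by lag-1 autocorrelation
#'   (`n_eff = n * (1 - r1x*r1y) / (1 + r1x*r1y)`).
#'
#' @return One-row tibble of class `corr_result`: `r`, `z`, `n`, `p` (and
#'   optionally `n_eff`, `p_ess`).
#' @export
correlate_series <- function(x, y, adjust_ess = FALSE) {
  if (is.data.frame(x)) x <- x$value
  if (is.data.frame(y)) y <- y$value
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 paired finite samples")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in input series")
  ct <- cor.test(x, y)
  out <- tibble(
    r = unname(ct$estimate),
    z = fisher_z(unname(ct$estimate)),
    n = n,
    p = ct$p.value
  )
  if (adjust_ess) {
    r1 <- ar1_fit(x) * ar1_fit(y)
    n_eff <- max(4, n * (1 - r1) / (1 + r1))
    t_stat <- out$r * sqrt((n_eff - 2) / max(1 - out$r^2, 1e-15))
    out$n_eff <- n_eff
    out$p_ess <- 2 * pt(-abs(t_stat), df = n_eff - 2)
  }
  class(out) <- c("corr_result", class(out))
  out
}

#' Paired comparison of Fisher z scores
#'
#' Two-sided paired t-test on per-subject differences between a reference
#' set of Fisher z scores (say, the correlation of the hemodynamic signal
#' with bER) and a comparison set (the correlation with another gas
#' metric).
#'
#' @param z_ref,z_other Equal-length numeric vectors of per-subject Fisher z
#'   scores (n >= 2).
#'
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p`, `n`, `degenerate`
#'   (TRUE when the differences have zero variance, in which case `t` and
#'   `p` are `NA`).
#' @export
paired_z_comparison <- function(z_ref, z_other) {
  if (length(z_ref) != length(z_other)) abort("inputs must have equal length")
  n <- length(z_ref)
  if (n < 2) abort("need at least 2 pairs")
  d <- z_ref - z_other
  if (sd(d) == 0) {
    return(tibble(mean_diff = mean(d), t = NA_real_, df = n - 1,
                  p = NA_real_, n = n, degenerate = TRUE))
  }
  tt <- t.test(z_ref, z_other, paired = TRUE)
  tibble(
    mean_diff = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    n = n,
    degenerate = FALSE
  )
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure over a vector of p-values: adjusted p-values are
#' monotone in the raw ranks, and hypotheses with adjusted p at or below
#' `q` are rejected.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (non-empty).
#' @param q Target false discovery rate (default 0.05).
#'
#' @return Tibble `p`, `p_adj`, `reject`, in the input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) abort("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p = p_values, p_adj = adj, reject = adj <= q)
}
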