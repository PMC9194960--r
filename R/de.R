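#' Two-group per-gene statistics
#'
#' Ordinary least-squares fit of a two-group comparison: per-gene effect
#' `log2FC = mean(group2) - mean(group1)`, pooled residual variance and
#' residual degrees of freedom `n1 + n2 - 2`.
#'
#' @param mat Numeric gene-by-sample matrix (log2 scale).
#' @param group Character/factor of length `ncol(mat)` with exactly two
#'   levels, at least 2 samples each.
#' @param ref Reference level subtracted from the other (default
#'   `"normal"` when present, otherwise the first level).
#' @return data.frame with `gene`, `log2fc`, `s2`, `df` and the unscaled
#'   standard-error factor in attribute `"stdev_unscaled"`.
#' @export
fit_two_group <- function(mat, group, ref = NULL) {
  mat <- as.matrix(mat)
  group <- as.character(group)
  if (length(group) != ncol(mat))
    stop("'group' must have one entry per sample column")
  lv <- unique(group)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (is.null(ref)) ref <- if ("normal" %in% lv) "normal" else lv[1L]
  if (!ref %in% lv) stop("reference level '", ref, "' not present")
  other <- setdiff(lv, ref)
  i1 <- group == ref
  i2 <- group == other
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  rss <- rowSums((mat[, i1, drop = FALSE] - m1)^2) +
    rowSums((mat[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(gene = rownames(mat), log2fc = m2 - m1, s2 = rss / df,
                    df = df, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "stdev_unscaled") <- sqrt(1 / n1 + 1 / n2)
  attr(out, "groups") <- c(ref = ref, other = other)
  out
}

#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`, with the asymptotic closed forms
#' for extreme `y`. Needed to match the variance of log-variances to the
#' log-F prior in [squeeze_variance()].
#'
#' @param y Positive target value(s).
#' @return `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NaN)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (-dif / x < 1e-10) break
    }
    x
  }, numeric(1L))
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-gene sample variances towards a common prior by modelling
#' `s2 ~ s0^2 * F(df, d0)`. The prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by matching the mean and variance of
#' `log(s2)` to the log-F distribution (digamma/trigamma moment
#' inversion). The posterior variance is
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`; when the variance of the
#' log-variances is no larger than what sampling alone explains, `d0` is
#' infinite and every posterior variance equals `s0^2`.
#'
#' @param s2 Per-gene sample variances (>= 10 genes).
#' @param df Residual degrees of freedom (scalar).
#' @return List with `d0`, `s0_sq` and `s2_post`.
#' @export
squeeze_variance <- function(s2, df) {
  if (length(s2) < 10L)
    stop("variance moderation needs an ensemble of >= 10 genes")
  if (all(s2 <= 0))
    stop("degenerate ensemble: all sample variances are zero")
  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s2_post <- if (is.finite(d0)) (d0 * s0_sq + df * s2) / (d0 + df)
  else rep(s0_sq, length(s2))
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post)
}

#' Moderated (or ordinary) two-group t-statistics
#'
#' @param fit Output of [fit_two_group()].
#' @param d0 Override the estimated prior degrees of freedom: `0` forces
#'   the ordinary t-statistic, `Inf` the fully-shrunk limit where every
#'   gene shares the prior variance. `NULL` (default) estimates `d0` from
#'   the data.
#' @return `fit` with columns `t`, `p` (two-sided), plus attributes `d0`
#'   and `s0_sq`.
#' @export
moderate_t <- function(fit, d0 = NULL) {
  su <- attr(fit, "stdev_unscaled")
  if (is.null(su)) stop("'fit' must come from fit_two_group()")
  if (!is.null(d0) && length(d0) == 1L && d0 == 0) {
    sq <- list(d0 = 0, s0_sq = NA_real_, s2_post = fit$s2)
  } else {
    sq <- squeeze_variance(fit$s2, fit$df[1L])
    if (!is.null(d0)) {  # forced prior df, prior variance re-estimated
      sq$d0 <- d0
      sq$s2_post <- if (is.finite(d0))
        (d0 * sq$s0_sq + fit$df * fit$s2) / (d0 + fit$df)
      else rep(sq$s0_sq, nrow(fit))
    }
  }
  se <- sqrt(sq$s2_post) * su
  t <- ifelse(se > 0, fit$log2fc / se, ifelse(fit$log2fc == 0, 0, Inf *
                                                sign(fit$log2fc)))
  df_total <- fit$df + sq$d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  fit$t <- t
  fit$p <- p
  attr(fit, "d0") <- sq$d0
  attr(fit, "s0_sq") <- sq$s0_sq
  fit
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation (checked in the tests against an O(m^2) textbook
#' step-up oracle and against `stats::p.adjust`): adjusted p-values are
#' `p_(i) * m / i` corrected to be monotone by a cumulative minimum from
#' the largest p downwards, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values aligned with the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Full two-group differential-expression analysis
#'
#' [fit_two_group()] + [moderate_t()] + [bh_adjust()], with the dual
#' significance rule `adj_p < alpha` and `|log2FC| >= lfc`.
#'
#' @param mat Gene-by-sample log2 matrix.
#' @param group Two-level group vector (see [fit_two_group()]).
#' @param alpha BH-FDR significance level (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param moderated Use the empirical-Bayes moderated t (default TRUE);
#'   FALSE gives the ordinary pooled-variance t for comparison.
#' @param ref Reference group level.
#' @return data.frame (`de_table`): `gene`, `log2fc`, `s2`, `t`, `p`,
#'   `adj_p`, `significant`, `direction` (`up` means higher in the
#'   non-reference group).
#' @export
de_analysis <- function(mat, group, alpha = 0.05, lfc = 1,
                        moderated = TRUE, ref = NULL) {
  fit <- fit_two_group(mat, group, ref = ref)
  fit <- moderate_t(fit, d0 = if (moderated) NULL else 0)
  fit$adj_p <- bh_adjust(fit$p)
  fit$significant <- fit$adj_p < alpha & abs(fit$log2fc) >= lfc
  fit$direction <- ifelse(fit$log2fc >= 0, "up", "down")
  attr(fit, "alpha") <- alpha
  attr(fit, "lfc") <- lfc
  class(fit) <- c("de_table", class(fit))
  fit
}

#' Select differential genes from a DE table
#'
#' @param results A `de_table` from [de_analysis()].
#' @param alpha,lfc Optional re-thresholding; defaults reuse the values the
#'   table was built with.
#' @return data.frame of significant genes sorted by p then gene id.
#' @export
select_de <- function(results, alpha = attr(results, "alpha"),
                      lfc = attr(results, "lfc")) {
  keep <- results$adj_p < alpha & abs(results$log2fc) >= lfc
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
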