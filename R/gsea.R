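#' Build a deterministic ranked list from rank scores
#'
#' Sorts a named rank-score vector into decreasing order, breaking ties by
#' gene id in the C locale so the ranked list is reproducible across
#' platforms and input orders.
#'
#' @param rs Named numeric vector of rank scores.
#' @return The same vector, sorted.
#' @export
build_ranked_list <- function(rs) {
  if (is.null(names(rs))) stop("'rs' must be a named vector")
  rs[order(-rs, names(rs), method = "radix")]
}

# Closed-form weighted KS enrichment score.
# w: |rs|^exponent on the ranked list (length N); pos: sorted hit positions.
# Hits step up by w[pos]/sum(w[pos]) (or 1/Nh if the hit weights sum to 0),
# misses step down by 1/(N - Nh) (0 when the set covers the whole list).
# The extreme deviations can only occur at a peak just after a hit or a
# valley just before one, so only 2*Nh candidates are examined. A tie in
# absolute deviation resolves to the positive excursion.
.gsea_es_core <- function(w, pos, N) {
  nh <- length(pos)
  hw <- w[pos]
  S <- sum(hw)
  inc <- if (S > 0) hw / S else rep(1 / nh, nh)
  mu <- if (N > nh) 1 / (N - nh) else 0
  cs <- cumsum(inc)
  gaps <- (pos - seq_len(nh)) * mu
  peaks <- cs - gaps
  valleys <- c(0, cs[-nh]) - gaps
  top <- max(peaks)
  bottom <- min(valleys, 0)
  # a 1e-9 window makes the positive-on-tie rule robust to float jitter
  if (top >= -bottom - 1e-9) top else bottom
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum statistic over a ranked gene list: members of `gene_set`
#' ("hits") increment the walk by their weight `|rs|^exponent` normalised
#' to the total hit weight, non-members decrement by `1/(N - Nh)`. The
#' enrichment score is the signed maximum deviation of the walk from zero.
#'
#' @param ranked_rs Named rank-score vector; re-sorted internally via
#'   [build_ranked_list()], so any order is accepted.
#' @param gene_set Character vector of gene ids.
#' @param exponent Weighting exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return The enrichment score in `[-1, 1]`, or `NA` when the set does
#'   not intersect the list.
#' @export
gsea_es <- function(ranked_rs, gene_set, exponent = 1) {
  rs <- build_ranked_list(ranked_rs)
  pos <- which(names(rs) %in% gene_set)
  if (length(pos) == 0L) return(NA_real_)
  .gsea_es_core(abs(rs)^exponent, pos, length(rs))
}

#' Gene-label permutation null for the enrichment score
#'
#' Draws `nperm` random gene sets of the observed intersection size from
#' the ranked list (equivalently, permutes gene labels) and returns their
#' enrichment scores. Uses the current RNG state; seed it with
#' [withr::with_seed()] or via the `seed` arguments of the callers.
#'
#' @param ranked_rs Sorted named rank-score vector (see
#'   [build_ranked_list()]).
#' @param n_hits Set size to draw.
#' @param nperm Number of permutations (>= 100 for a usable p-value).
#' @param exponent Weighting exponent.
#' @return Numeric vector of `nperm` null enrichment scores.
#' @export
gsea_null_es <- function(ranked_rs, n_hits, nperm, exponent = 1) {
  N <- length(ranked_rs)
  stopifnot(n_hits >= 1L, n_hits <= N)
  w <- abs(ranked_rs)^exponent
  mu <- if (N > n_hits) 1 / (N - n_hits) else 0
  P <- vapply(seq_len(nperm),
              function(i) sort.int(sample.int(N, n_hits)),
              integer(n_hits))
  P <- matrix(P, nrow = n_hits)           # n_hits x nperm
  W <- matrix(w[P], nrow = n_hits)
  S <- colSums(W)
  CS <- apply(W, 2L, cumsum)
  CS <- matrix(CS, nrow = n_hits)
  zero <- S <= 0
  if (any(zero)) {
    CS[, zero] <- matrix(rep(seq_len(n_hits) / n_hits, sum(zero)),
                         nrow = n_hits)
    S[zero] <- 1
  }
  CS <- sweep(CS, 2L, S, "/")
  gaps <- (P - seq_len(n_hits)) * mu
  peaks <- CS - gaps
  valleys <- rbind(0, CS[-n_hits, , drop = FALSE]) - gaps
  top <- apply(peaks, 2L, max)
  bottom <- pmin(apply(valleys, 2L, min), 0)
  ifelse(top >= -bottom - 1e-9, top, bottom)
}

#' Permutation p-value for an observed enrichment score
#'
#' Sign-matched estimator: `p = (1 + #{same-sign null with |es*| >= |es|})
#' / (1 + #same-sign null)`. An observed score of exactly zero (or with no
#' same-sign permutations) gets `p = 1`. The estimator is bounded below by
#' `1/(1 + nperm)`.
#'
#' @param es Observed enrichment score.
#' @param null_es Null scores from [gsea_null_es()].
#' @return p-value in `(0, 1]`.
#' @export
gsea_perm_p <- function(es, null_es) {
  if (is.na(es) || es == 0) return(1)
  same <- if (es > 0) null_es > 0 else null_es < 0
  n_same <- sum(same)
  if (n_same == 0L) return(1)
  exceed <- sum(abs(null_es[same]) >= abs(es))
  (1 + exceed) / (1 + n_same)
}
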