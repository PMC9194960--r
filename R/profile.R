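#' Single-sample gene-set variation scores
#'
#' Non-parametric per-sample pathway activity, following the
#' kernel-CDF/rank random-walk construction: (1) each gene's expression is
#' converted to a relative statistic via a Gaussian-kernel cumulative
#' density across samples with bandwidth `sd/4`; (2) within each sample,
#' genes are ranked by that statistic and the ranks are symmetrized about
#' the centre, so both extremes of the distribution carry large weight;
#' (3) for each gene set and sample a weighted Kolmogorov-Smirnov random
#' walk is run down the ranking (hit weight `|r|^tau`, miss penalty
#' `1/(N - Nh)`); the score is the difference between the maximum positive
#' and maximum negative deviation (`"mx.diff"`, the default) or the
#' single largest-magnitude deviation (`"sign.max"`).
#'
#' Constant genes receive a flat statistic and cannot discriminate
#' samples. Sets with no genes in the matrix are skipped with a message.
#'
#' @param expr Gene-by-sample log2 matrix, >= 3 samples.
#' @param collection A [gene_set_collection()].
#' @param tau Rank-weight exponent (default 1).
#' @param method `"mx.diff"` or `"sign.max"`.
#' @return Set-by-sample score matrix.
#' @export
gsva_scores <- function(expr, collection, tau = 1,
                        method = c("mx.diff", "sign.max")) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "gene_set_collection"))
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 3L) stop("density estimation across samples needs >= 3 samples")
  N <- nrow(expr)
  # kernel-CDF statistic per gene
  z <- t(vapply(seq_len(N), function(i) {
    x <- expr[i, ]
    h <- stats::sd(x) / 4
    if (!is.finite(h) || h == 0) return(rep(0.5, n))
    rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }, numeric(n)))
  dimnames(z) <- dimnames(expr)
  # symmetrized rank statistic per sample
  r <- apply(z, 2L, function(col) {
    rk <- rank(-col, ties.method = "first")    # 1 = highest statistic
    abs(N / 2 - rk + 0.5)
  })
  sets <- collection$sets
  present <- vapply(sets, function(g) sum(g %in% rownames(expr)),
                    integer(1L))
  if (any(present == 0L)) {
    message(sum(present == 0L),
            " gene set(s) with no genes in the matrix skipped")
    sets <- sets[present > 0L]
  }
  if (length(sets) == 0L) stop("no scorable gene sets")
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  gene_ids <- rownames(expr)
  for (si in seq_along(sets)) {
    hit <- gene_ids %in% sets[[si]]
    nh <- sum(hit)
    mu <- if (N > nh) 1 / (N - nh) else 0
    for (j in seq_len(n)) {
      ord <- order(-z[, j], gene_ids, method = "radix")
      w <- r[ord, j]^tau
      h <- hit[ord]
      pos <- which(h)
      S <- sum(w[pos])
      inc <- if (S > 0) w[pos] / S else rep(1 / nh, nh)
      cs <- cumsum(inc)
      gaps <- (pos - seq_len(nh)) * mu
      peak <- max(cs - gaps, 0)
      valley <- min(c(0, cs[-nh]) - gaps, 0)
      out[si, j] <- if (method == "mx.diff") peak + valley
      else if (peak >= -valley) peak else valley
    }
  }
  out
}

#' Marker-based immune-cell abundance scores
#'
#' One score per cell population and sample: the arithmetic mean of the
#' log2 expression of the population's marker genes detected in the
#' matrix. Exactly linear in the marker sub-matrix. Populations with no
#' detected marker are omitted with a warning.
#'
#' @param expr Gene-by-sample log2 matrix.
#' @param markers A [gene_set_collection()] of marker sets (10
#'   populations by default in the shipped stand-in collection).
#' @return Population-by-sample score matrix.
#' @export
cell_scores <- function(expr, markers) {
  stopifnot(inherits(markers, "gene_set_collection"))
  expr <- as.matrix(expr)
  rows <- lapply(names(markers$sets), function(nm) {
    g <- intersect(markers$sets[[nm]], rownames(expr))
    if (length(g) == 0L) return(NULL)
    colMeans(expr[g, , drop = FALSE])
  })
  names(rows) <- names(markers$sets)
  empty <- vapply(rows, is.null, logical(1L))
  if (any(empty))
    warning("population(s) with no detected marker omitted: ",
            paste(names(rows)[empty], collapse = ", "), call. = FALSE)
  if (all(empty)) stop("no population has detected markers")
  do.call(rbind, rows[!empty])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution (via the signed-rank/rank-sum distribution
#' functions) whenever there are no ties and both groups have <= `exact_max`
#' observations; otherwise the normal approximation with mid-ranks and the
#' tie-corrected variance. Two completely tied groups give p = 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact distribution
#'   (default 10).
#' @return List with `statistic` (rank-sum W of `x`, centred form used by
#'   the normal approximation) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y), ties.method = "average")
  ties <- anyDuplicated(c(x, y)) > 0L
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(stats::pwilcox(W, n1, n2),
                 stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (W - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = W, p = p)
}

#' Compare pathway and cell-population scores between two subtypes
#'
#' Per-feature two-sided Wilcoxon rank-sum test (exact for small groups,
#' see [wilcoxon_rank_sum()]) between the samples of the two subtype
#' labels, with a BH-free significance call at `alpha` (matching the
#' published per-feature P < 0.05 annotations). A t-test alternative is
#' available.
#'
#' @param scores Feature-by-sample matrix (e.g. from [gsva_scores()] or
#'   [cell_scores()]).
#' @param labels Named vector (sample -> subtype), exactly two distinct
#'   labels with >= 2 samples each.
#' @param class_label Label written into the `class` column (`"pathway"`
#'   or `"cell"`).
#' @param alpha Significance level (default 0.05).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return data.frame: `feature`, `class`, `statistic`, `p`,
#'   `significant`.
#' @export
compare_subtypes <- function(scores, labels, class_label = "pathway",
                             alpha = 0.05, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("exactly two subtype labels required")
  if (any(table(as.character(labels)) < 2L))
    stop("each subtype needs >= 2 samples")
  scores <- as.matrix(scores)[, names(labels), drop = FALSE]
  i1 <- as.character(labels) == lv[1L]
  res <- lapply(seq_len(nrow(scores)), function(i) {
    x <- scores[i, i1]
    y <- scores[i, !i1]
    if (test == "wilcoxon") {
      wt <- wilcoxon_rank_sum(x, y)
      c(wt$statistic, wt$p)
    } else {
      tt <- stats::t.test(x, y)
      c(unname(tt$statistic), tt$p.value)
    }
  })
  res <- do.call(rbind, res)
  data.frame(feature = rownames(scores), class = class_label,
             statistic = res[, 1L], p = res[, 2L],
             significant = res[, 2L] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
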