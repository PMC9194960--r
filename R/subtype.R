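#' Consensus clustering by repeated subsampling
#'
#' For each of `reps` repetitions, a random `ceiling(p_item * n)`-sample
#' (and, when `p_feature < 1`, `ceiling(p_feature * m)`-feature) subset is
#' clustered by agglomerative hierarchical clustering (euclidean distance,
#' average linkage by default) cut at each `k` in `k_range`. The consensus
#' value for a sample pair at a given `k` is the fraction of repetitions
#' containing both samples in which they landed in the same cluster. The
#' same subsamples are reused across all `k`, as the reference
#' implementation does. Final labels come from hierarchical clustering of
#' `1 - consensus`; the number of clusters is either fixed (`final_k`) or
#' chosen by the relative delta of the consensus CDF area (the area for
#' `k = 2`, then `(A_k - A_{k-1}) / A_{k-1}` for larger `k`; the `k`
#' maximizing this is selected).
#'
#' @param mat Feature-by-sample matrix (e.g. immune-related differential
#'   lncRNAs over the pulpitis cohort).
#' @param k_range Candidate cluster numbers (min >= 2; values above
#'   `n - 1` are dropped with a warning).
#' @param reps Subsampling repetitions (published setting: 1000).
#' @param p_item Sample subsampling proportion (published setting: 0.8).
#' @param p_feature Feature subsampling proportion (published setting: 1).
#' @param linkage Hierarchical linkage for both the inner and the final
#'   clustering (default `"average"`).
#' @param inner `"hclust"` (default) or `"kmeans"` for the per-repetition
#'   clusterer.
#' @param final_k Fixed final `k`; `NULL` (default) selects by delta area.
#' @param seed Optional seed making the subsampling reproducible.
#' @return Object of class `consensus_result`: `k_range`, `consensus`
#'   (named list of sample-by-sample matrices in `[0, 1]`, symmetric, unit
#'   diagonal), `area` and `delta_area` per k, `selected_k`, and `labels`
#'   (named integer vector for `final_k %||% selected_k`).
#' @export
consensus_cluster <- function(mat, k_range = 2:6, reps = 1000L,
                              p_item = 0.8, p_feature = 1,
                              linkage = "average",
                              inner = c("hclust", "kmeans"),
                              final_k = NULL, seed = NULL) {
  inner <- match.arg(inner)
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (min(k_range) < 2L) stop("k_range minimum must be >= 2")
  if (any(k_range > n - 1L)) {
    warning("dropping k values above n - 1", call. = FALSE)
    k_range <- k_range[k_range <= n - 1L]
    if (length(k_range) == 0L) stop("no feasible k in k_range")
  }
  k_range <- sort(unique(as.integer(k_range)))
  samples <- colnames(mat)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  n_item <- ceiling(p_item * n)
  n_feat <- ceiling(p_feature * nrow(mat))
  run <- function() {
    conn <- lapply(k_range, function(k) matrix(0, n, n))
    names(conn) <- as.character(k_range)
    together <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, n_item))
      feat <- if (n_feat < nrow(mat)) sort(sample.int(nrow(mat), n_feat))
      else seq_len(nrow(mat))
      together[idx, idx] <- together[idx, idx] + 1
      sub <- mat[feat, idx, drop = FALSE]
      d <- stats::dist(t(sub))
      hc <- if (inner == "hclust") stats::hclust(d, method = linkage)
      else NULL
      for (ks in as.character(k_range)) {
        k <- as.integer(ks)
        cl <- if (inner == "hclust") stats::cutree(hc, k = k)
        else stats::kmeans(t(sub), centers = min(k, n_item))$cluster
        same <- outer(cl, cl, "==")
        conn[[ks]][idx, idx] <- conn[[ks]][idx, idx] + same
      }
    }
    list(conn = conn, together = together)
  }
  acc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  never <- acc$together == 0 & upper.tri(acc$together)
  if (any(never))
    warning(sum(never), " sample pair(s) never co-subsampled; their ",
            "consensus is defined as 0", call. = FALSE)
  consensus <- lapply(acc$conn, function(cm) {
    out <- ifelse(acc$together > 0, cm / acc$together, 0)
    diag(out) <- 1
    out <- (out + t(out)) / 2
    dimnames(out) <- list(samples, samples)
    out
  })
  area <- vapply(consensus, consensus_cdf_area, numeric(1L))
  delta <- numeric(length(k_range))
  delta[1L] <- area[1L]
  if (length(k_range) > 1L)
    delta[-1L] <- diff(area) / area[-length(area)]
  names(delta) <- names(area)
  selected_k <- k_range[which.max(delta)]
  use_k <- if (is.null(final_k)) selected_k else as.integer(final_k)
  labels <- consensus_labels(consensus[[as.character(use_k)]], use_k,
                             linkage = linkage)
  structure(list(k_range = k_range, consensus = consensus, area = area,
                 delta_area = delta, selected_k = selected_k,
                 final_k = use_k, labels = labels),
            class = "consensus_result")
}

# Empirical-CDF area of the upper-triangular consensus values.
consensus_cdf_area <- function(cm) {
  v <- sort(cm[upper.tri(cm)])
  if (length(v) == 0L) return(0)
  x <- c(0, v, 1)
  f <- stats::ecdf(v)
  sum(diff(x) * f(x[-length(x)]))
}

#' Cut a consensus matrix into final cluster labels
#'
#' @param consensus Sample-by-sample consensus matrix.
#' @param k Number of clusters.
#' @param linkage Hierarchical linkage (default `"average"`).
#' @return Named integer vector of cluster labels.
#' @export
consensus_labels <- function(consensus, k, linkage = "average") {
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = linkage)
  stats::cutree(hc, k = k)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, selected k = %d, %d samples\n",
              paste(x$k_range, collapse = ","), x$selected_k,
              length(x$labels)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' PCA embedding of samples
#'
#' Column-centred singular value decomposition of the sample profiles;
#' scores are `U %*% S`. Used to visually validate a clustering: well
#' separated clusters separate along the leading components.
#'
#' @param mat Feature-by-sample matrix with >= 3 samples.
#' @return List with `scores` (samples x PCs), `var_explained`
#'   (non-increasing, sums to <= 1) and `sdev`.
#' @export
pca_embed <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop("PCA needs >= 3 samples")
  if (all(apply(mat, 1L, stats::sd) == 0))
    stop("constant matrix: PCA undefined")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve, sdev = pc$sdev,
       rotation = pc$rotation)
}

#' Differential expression between two subtypes
#'
#' Re-uses the moderated-t machinery between cluster 1 and cluster 2 of a
#' labelled cohort, separately for the mRNA and lncRNA matrices, and
#' returns the `top_n` genes with the lowest p-values together with
#' row-z-scored expression sub-matrices ready for heatmap export.
#'
#' @param bundle An [expression_bundle()] (or any list with `mrna` and
#'   `lnc` matrices).
#' @param labels Named vector (sample -> cluster) with exactly two
#'   distinct labels, each backed by >= 2 samples.
#' @param top_n Genes to report per biotype (default 50; clamped to the
#'   gene count).
#' @param ... Passed to [de_analysis()] (e.g. `moderated = FALSE`).
#' @return List with elements `mrna` and `lnc`, each holding `table` (full
#'   DE table), `top` (top_n rows by p) and `zmat` (z-scored expression of
#'   the top genes over the labelled samples).
#' @export
subtype_de <- function(bundle, labels, top_n = 50L, ...) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) stop("exactly two subtype labels required")
  if (any(table(as.character(labels)) < 2L))
    stop("each subtype needs >= 2 samples")
  samp <- names(labels)
  grp <- paste0("subtype", match(as.character(labels), lv))
  one <- function(mat) {
    m <- mat[, samp, drop = FALSE]
    tab <- de_analysis(m, grp, ref = "subtype1", ...)
    ord <- order(tab$p, tab$gene, method = "radix")
    top <- tab[ord[seq_len(min(top_n, nrow(tab)))], , drop = FALSE]
    rownames(top) <- NULL
    z <- m[top$gene, , drop = FALSE]
    mu <- rowMeans(z)
    sd <- apply(z, 1L, stats::sd)
    zmat <- (z - mu) / ifelse(sd > 0, sd, 1)
    list(table = tab, top = top, zmat = zmat)
  }
  list(mrna = one(bundle$mrna), lnc = one(bundle$lnc))
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' permutation), ~0 for independent ones.
#'
#' @param a,b Two label vectors over the same items (matched by names when
#'   both are named).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
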