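#' Pairwise lncRNA-mRNA correlation
#'
#' Pearson (default) or Spearman correlation of every lncRNA against every
#' mRNA across the shared samples, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Zero-variance genes yield `cc = 0, p = 1` (no evidence either way);
#' perfect correlations are floored at `p_min` so the rank score stays
#' finite.
#'
#' @param lnc_mat lncRNA-by-sample matrix.
#' @param mrna_mat mRNA-by-sample matrix, same samples in the same order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param p_min Floor applied to p-values (default 1e-300).
#' @return List with matrices `cc` and `p`, both lncRNA x mRNA.
#' @export
correlate <- function(lnc_mat, mrna_mat, method = c("pearson", "spearman"),
                      p_min = 1e-300) {
  method <- match.arg(method)
  if (!identical(colnames(lnc_mat), colnames(mrna_mat)))
    stop("matrices must share identical, identically ordered samples")
  n <- ncol(lnc_mat)
  if (n < 4L) stop("need >= 4 shared samples for a usable correlation p-value")
  cc <- suppressWarnings(stats::cor(t(lnc_mat), t(mrna_mat),
                                    method = method))
  cc[is.na(cc)] <- 0                       # zero-variance genes
  cc <- pmin(pmax(cc, -1), 1)
  tstat <- cc * sqrt((n - 2) / pmax(1 - cc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[cc == 0] <- 1
  p <- pmax(p, p_min)
  list(cc = cc, p = p)
}

#' Rank score for one lncRNA-mRNA pair
#'
#' `RS = -log10(p) * sign(cc)`: large positive for strong positive
#' correlation, large negative for strong negative correlation, zero for
#' uncorrelated pairs. p-values are floored at `p_min` before the log, so
#' the score is capped at `-log10(p_min)` (300 by default).
#'
#' @param cc Correlation coefficient(s) in `[-1, 1]`.
#' @param p Correlation p-value(s) in `(0, 1]`.
#' @param p_min Floor applied before taking the log.
#' @return Numeric rank score(s).
#' @export
rank_score <- function(cc, p, p_min = 1e-300) {
  -log10(pmax(p, p_min)) * sign(cc)
}

#' lncRES transform of an enrichment result
#'
#' Maps an enrichment score and its p-value onto `[-1, 1]`:
#' `1 - 2p` for positive enrichment, `2p - 1` for negative enrichment, and
#' 0 for the degenerate `es = 0` case (which can therefore never pass a
#' positive significance cutoff). Strictly decreasing in `p` when
#' `es > 0`, strictly increasing when `es < 0`.
#'
#' @param es Enrichment score(s).
#' @param p Enrichment p-value(s) in `[0, 1]`.
#' @return lncRES value(s) in `[-1, 1]`.
#' @export
lncres_transform <- function(es, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  out <- ifelse(es > 0, 1 - 2 * p, ifelse(es < 0, 2 * p - 1, 0))
  out[is.na(es)] <- NA_real_
  out
}

#' Default lncRES scoring parameters
#'
#' The significance rule is the published one: a pair is significant when
#' `lncRES > 0.995` (i.e. enrichment p below 0.0025 with positive ES) and
#' its BH false-discovery rate is below 0.05.
#'
#' @return Named list of defaults used by [lncres_score()].
#' @export
lncres_params <- function() {
  list(method = "pearson", p_min = 1e-300, exponent = 1,
       min_set_size = 5L, nperm = 1000L, lncres_cut = 0.995,
       fdr_cut = 0.05, fdr_scope = "lnc")
}

#' Score every lncRNA against every gene set (lncRES)
#'
#' The core pipeline statistic. For each lncRNA: correlate it with every
#' mRNA, convert each pair to a rank score, sort all mRNAs by that score
#' (ties broken by gene id), run weighted KS enrichment of each gene set
#' against the ranked list, estimate the enrichment p-value by gene-label
#' permutation, and transform to the lncRES score. Permutation draws are
#' shared across sets of equal intersection size within one lncRNA.
#'
#' FDR is Benjamini-Hochberg either per lncRNA across its gene sets
#' (`fdr_scope = "lnc"`, the default: this matches running one enrichment
#' analysis per lncRNA and adjusting within the run) or across the whole
#' lncRNA x set table (`"global"`). A record is significant when
#' `lncres > lncres_cut` and `fdr < fdr_cut`; an "immune-related lncRNA"
#' is any lncRNA with at least one significant record.
#'
#' lncRNAs are processed in lexicographic id order, so results are
#' invariant to the row order of the input matrices and (given aligned
#' columns) to sample order.
#'
#' @param lnc_mat,mrna_mat Sample-aligned expression matrices.
#' @param collection A [gene_set_collection()] of mRNA sets.
#' @param method,p_min,exponent,min_set_size,nperm,lncres_cut,fdr_cut,fdr_scope
#'   See [lncres_params()]; `min_set_size` drops lncRNA/set pairs whose
#'   set intersects fewer ranked mRNAs than this.
#' @param seed Optional integer; when given, the permutation stream is
#'   seeded and results are reproducible.
#' @param verbose Emit a message with the number of skipped sets.
#' @return data.frame of class `lncres_table`: `lnc`, `set`, `category`,
#'   `n_hits`, `es`, `p`, `lncres`, `fdr`, `significant`.
#' @export
lncres_score <- function(lnc_mat, mrna_mat, collection,
                         method = "pearson", p_min = 1e-300, exponent = 1,
                         min_set_size = 5L, nperm = 1000L,
                         lncres_cut = 0.995, fdr_cut = 0.05,
                         fdr_scope = c("lnc", "global"),
                         seed = NULL, verbose = FALSE) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (nperm < 100L) stop("nperm must be >= 100")
  corr <- correlate(lnc_mat, mrna_mat, method = method, p_min = p_min)
  rs_mat <- rank_score(corr$cc, corr$p, p_min = p_min)
  lnc_ids <- sort(rownames(lnc_mat), method = "radix")
  run <- function() {
    skipped <- 0L
    rows <- vector("list", length(lnc_ids))
    for (li in seq_along(lnc_ids)) {
      lnc <- lnc_ids[li]
      ranked <- build_ranked_list(rs_mat[lnc, ])
      ranked_ids <- names(ranked)
      w <- abs(ranked)^exponent
      pos_list <- lapply(collection$sets, function(g)
        which(ranked_ids %in% g))
      sizes <- lengths(pos_list)
      keep <- sizes >= min_set_size
      skipped <- skipped + sum(!keep)
      if (!any(keep)) next
      null_by_size <- list()
      es <- p <- numeric(sum(keep))
      kept_names <- names(pos_list)[keep]
      for (si in seq_along(kept_names)) {
        nm <- kept_names[si]
        pos <- pos_list[[nm]]
        es[si] <- .gsea_es_core(w, pos, length(ranked))
        key <- as.character(length(pos))
        if (is.null(null_by_size[[key]]))
          null_by_size[[key]] <- gsea_null_es(ranked, length(pos), nperm,
                                              exponent = exponent)
        p[si] <- gsea_perm_p(es[si], null_by_size[[key]])
      }
      rows[[li]] <- data.frame(
        lnc = lnc, set = kept_names,
        category = unname(collection$category[kept_names]),
        n_hits = unname(sizes[keep]), es = es, p = p,
        stringsAsFactors = FALSE)
    }
    list(tab = do.call(rbind, rows), skipped = skipped)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (verbose && res$skipped > 0L)
    message(res$skipped, " lncRNA/set pair(s) below min_set_size skipped")
  tab <- res$tab
  if (is.null(tab))
    tab <- data.frame(lnc = character(), set = character(),
                      category = character(), n_hits = integer(),
                      es = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  tab$lncres <- lncres_transform(tab$es, tab$p)
  tab$fdr <- if (nrow(tab) == 0L) numeric(0)
  else if (fdr_scope == "global") bh_adjust(tab$p)
  else stats::ave(tab$p, tab$lnc, FUN = bh_adjust)
  tab$significant <- tab$lncres > lncres_cut & tab$fdr < fdr_cut
  rownames(tab) <- NULL
  attr(tab, "params") <- list(method = method, p_min = p_min,
                              exponent = exponent,
                              min_set_size = min_set_size, nperm = nperm,
                              lncres_cut = lncres_cut, fdr_cut = fdr_cut,
                              fdr_scope = fdr_scope, seed = seed)
  class(tab) <- c("lncres_table", class(tab))
  tab
}

#' Immune-related lncRNAs from a scored table
#'
#' @param records An `lncres_table` from [lncres_score()].
#' @return Sorted character vector of lncRNAs with at least one
#'   significant record.
#' @export
immune_lnc_ids <- function(records) {
  sort(unique(records$lnc[records$significant]), method = "radix")
}

#' Intersect immune-related lncRNAs with differential lncRNAs
#'
#' @param immune_ids,de_ids Two character id sets.
#' @return List with the sorted `overlap` and the Venn counts `n_a`,
#'   `n_b`, `n_overlap`.
#' @export
intersect_with_de <- function(immune_ids, de_ids) {
  ov <- sort(intersect(immune_ids, de_ids), method = "radix")
  list(overlap = ov, n_a = length(unique(immune_ids)),
       n_b = length(unique(de_ids)), n_overlap = length(ov))
}

#' Cross-dataset agreement of two lncRES tables
#'
#' Measures how well two independently scored cohorts agree: the Jaccard
#' index of their significant lncRNA sets, and the Spearman rank
#' correlation of lncRES values over the shared (lncRNA, set) pairs.
#'
#' @param records_a,records_b Two `lncres_table`s over shared lncRNA ids.
#' @return List with `jaccard`, `rank_cor`, `n_shared_pairs`.
#' @export
overlap_validation <- function(records_a, records_b) {
  a <- immune_lnc_ids(records_a)
  b <- immune_lnc_ids(records_b)
  un <- union(a, b)
  jac <- if (length(un) == 0L) 1 else length(intersect(a, b)) / length(un)
  key_a <- paste(records_a$lnc, records_a$set, sep = "\r")
  key_b <- paste(records_b$lnc, records_b$set, sep = "\r")
  shared <- intersect(key_a, key_b)
  rc <- if (length(shared) >= 3L)
    stats::cor(records_a$lncres[match(shared, key_a)],
               records_b$lncres[match(shared, key_b)],
               method = "spearman")
  else NA_real_
  list(jaccard = jac, rank_cor = rc, n_shared_pairs = length(shared))
}
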