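#' Paired lncRNA/mRNA expression bundle
#'
#' The object every analysis stage consumes: a lncRNA log2 expression
#' matrix, an mRNA log2 expression matrix, and a sample design table with a
#' `condition` column (`normal` / `pulpitis`) and an optional `dataset`
#' tag. Samples (columns) must be identical and identically ordered across
#' the two matrices and the design.
#'
#' @param lnc_matrix Numeric matrix, lncRNAs in rows, samples in columns.
#' @param mrna_matrix Numeric matrix, mRNAs in rows, same columns.
#' @param design data.frame with columns `sample_id`, `condition` and
#'   optionally `dataset`.
#' @param require_groups If TRUE (default) insist on >= 2 samples per
#'   condition, the minimum any two-group statistic needs.
#'
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(lnc_matrix, mrna_matrix, design,
                              require_groups = TRUE) {
  lnc_matrix <- as.matrix(lnc_matrix)
  mrna_matrix <- as.matrix(mrna_matrix)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("design must have columns 'sample_id' and 'condition'")
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  for (nm in c("lnc", "mrna")) {
    m <- if (nm == "lnc") lnc_matrix else mrna_matrix
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop(nm, " matrix must have row and column names")
    if (anyDuplicated(rownames(m)))
      stop("duplicate gene ids in ", nm, " matrix: ",
           paste(utils::head(unique(rownames(m)[duplicated(rownames(m))]), 5),
                 collapse = ", "))
  }
  if (!identical(colnames(lnc_matrix), colnames(mrna_matrix)))
    stop("sample columns differ between lncRNA and mRNA matrices")
  if (!identical(colnames(lnc_matrix), design$sample_id)) {
    bad <- union(setdiff(colnames(lnc_matrix), design$sample_id),
                 setdiff(design$sample_id, colnames(lnc_matrix)))
    stop("samples mismatch between matrices and design: ",
         paste(bad, collapse = ", "))
  }
  bad_cond <- setdiff(unique(design$condition), c("normal", "pulpitis"))
  if (length(bad_cond))
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  if (require_groups) {
    tab <- table(design$condition)
    if (any(tab < 2L) || length(tab) < 2L)
      stop("need >= 2 samples in each of 'normal' and 'pulpitis'")
  }
  structure(list(lnc = lnc_matrix, mrna = mrna_matrix, design = design),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  tab <- table(x$design$condition)
  cat(sprintf("expression_bundle: %d lncRNAs, %d mRNAs, %d samples (%s)\n",
              nrow(x$lnc), nrow(x$mrna), ncol(x$lnc),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset a bundle to a set of samples
#'
#' @param bundle An [expression_bundle()].
#' @param samples Character vector of sample ids to keep (order preserved).
#' @param require_groups Passed through to the constructor; set FALSE for
#'   single-condition cohorts (e.g. the pulpitis-only clustering matrix).
#' @return A new `expression_bundle`.
#' @export
subset_samples <- function(bundle, samples, require_groups = FALSE) {
  stopifnot(inherits(bundle, "expression_bundle"))
  missing <- setdiff(samples, bundle$design$sample_id)
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  d <- bundle$design[match(samples, bundle$design$sample_id), , drop = FALSE]
  rownames(d) <- NULL
  expression_bundle(bundle$lnc[, samples, drop = FALSE],
                    bundle$mrna[, samples, drop = FALSE],
                    d, require_groups = require_groups)
}

# ---- TSV readers/writers -------------------------------------------------

#' Write / read an expression matrix as TSV
#'
#' Genes in rows, first column `gene_id`, remaining columns one per sample.
#' Full double precision is preserved (values are written with \code{format
#' digits = 17}), so write-then-read round-trips exactly.
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns the matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write: ", path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression TSV not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write / read a sample design table as TSV
#'
#' @param design data.frame with `sample_id`, `condition` and optional
#'   further columns.
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop("design TSV not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Assemble an expression bundle from files or objects
#'
#' Reads a single gene-by-sample expression table plus a design table and
#' splits genes into the lncRNA and mRNA matrices using a biotype map.
#' Genes absent from the map are dropped (count reported via `message`);
#' duplicated gene ids are collapsed to the row with the largest mean
#' expression, standard practice for probe-collapsed array data.
#'
#' @param expr Path to an expression TSV or a numeric matrix.
#' @param design Path to a design TSV or a data.frame.
#' @param biotype Named character vector mapping gene id to `"lncRNA"` or
#'   `"mRNA"` (or a two-column data.frame `gene_id`, `biotype`).
#' @return An [expression_bundle()].
#' @export
read_expression <- function(expr, design, biotype) {
  m <- if (is.character(expr)) read_expression_tsv(expr) else as.matrix(expr)
  d <- if (is.character(design)) read_design_tsv(design) else
    as.data.frame(design, stringsAsFactors = FALSE)
  if (is.data.frame(biotype)) {
    biotype <- stats::setNames(as.character(biotype[[2L]]),
                               as.character(biotype[[1L]]))
  }
  m <- collapse_duplicate_genes(m)
  bt <- biotype[rownames(m)]
  unmapped <- sum(is.na(bt))
  if (unmapped > 0L)
    message(unmapped, " gene id(s) missing from the biotype map were dropped")
  keep <- !is.na(bt)
  m <- m[keep, , drop = FALSE]
  bt <- bt[keep]
  bad <- setdiff(unique(bt), c("lncRNA", "mRNA"))
  if (length(bad)) stop("unknown biotype label(s): ", paste(bad, collapse = ", "))
  samp <- d$sample_id
  if (!setequal(colnames(m), samp)) {
    bad <- union(setdiff(colnames(m), samp), setdiff(samp, colnames(m)))
    stop("samples mismatch between matrix and design: ",
         paste(bad, collapse = ", "))
  }
  m <- m[, samp, drop = FALSE]
  expression_bundle(m[bt == "lncRNA", , drop = FALSE],
                    m[bt == "mRNA", , drop = FALSE], d)
}

# Collapse duplicated gene ids keeping the row with the largest mean.
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  means <- rowMeans(m)
  ord <- order(rownames(m), -means, method = "radix")
  m2 <- m[ord, , drop = FALSE]
  m2[!duplicated(rownames(m2)), , drop = FALSE]
}

#' Read a simulated/exported fixture directory back into memory
#'
#' Counterpart of [write_fixture()]: expects `lnc_expression.tsv`,
#' `mrna_expression.tsv`, `design.tsv` and `immune_sets.gmt` under `dir`.
#'
#' @param dir Fixture directory.
#' @return List with `bundle` and `immune_sets` (plus `cell_markers` and
#'   `truth` when those files are present).
#' @export
read_fixture <- function(dir) {
  b <- expression_bundle(
    read_expression_tsv(file.path(dir, "lnc_expression.tsv")),
    read_expression_tsv(file.path(dir, "mrna_expression.tsv")),
    read_design_tsv(file.path(dir, "design.tsv")))
  out <- list(bundle = b,
              immune_sets = read_gmt(file.path(dir, "immune_sets.gmt")))
  mk <- file.path(dir, "cell_markers.gmt")
  if (file.exists(mk)) out$cell_markers <- read_gmt(mk)
  tr <- file.path(dir, "truth.json")
  if (file.exists(tr)) out$truth <- read_truth(tr)
  out
}

# ---- precleaning ---------------------------------------------------------

#' Preclean an expression bundle
#'
#' Applies, per matrix: (a) `log2(x + 1)` when the matrix maximum exceeds
#' 50 (a value no log2 microarray intensity reaches, so the rule detects
#' raw-scale input); (b) removal of rows containing missing values (small-n
#' arrays make imputation risky); (c) removal of rows with interquartile
#' range below `min_iqr`; (d) optional quantile normalization across
#' samples; (e) deterministic lexicographic row order. Idempotent: applying
#' it twice equals applying it once.
#'
#' @param bundle An [expression_bundle()].
#' @param min_iqr Minimum interquartile range a gene must have to be kept
#'   (log2 units). Default 0 keeps every finite row.
#' @param quantile_normalize Apply quantile normalization (default FALSE).
#' @return A precleaned `expression_bundle`.
#' @export
preclean <- function(bundle, min_iqr = 0, quantile_normalize = FALSE) {
  stopifnot(inherits(bundle, "expression_bundle"))
  clean1 <- function(m, what) {
    if (max(m, na.rm = TRUE) > 50) m <- log2(m + 1)
    has_na <- rowSums(is.na(m)) > 0L
    if (any(has_na)) {
      warning(sum(has_na), " ", what,
              " row(s) with missing values dropped", call. = FALSE)
      m <- m[!has_na, , drop = FALSE]
    }
    iqr <- apply(m, 1L, stats::IQR)
    m <- m[iqr >= min_iqr, , drop = FALSE]
    if (nrow(m) == 0L)
      stop("no ", what, " rows left after precleaning (min_iqr = ",
           min_iqr, ")")
    if (quantile_normalize) m <- quantile_normalize_matrix(m)
    m[order(rownames(m), method = "radix"), , drop = FALSE]
  }
  expression_bundle(clean1(bundle$lnc, "lncRNA"),
                    clean1(bundle$mrna, "mRNA"),
                    bundle$design)
}

# Plain quantile normalization: each column's sorted values are replaced by
# the mean sorted profile; ties receive the mean of the tied targets.
quantile_normalize_matrix <- function(m) {
  n <- nrow(m)
  ranks <- apply(m, 2L, rank, ties.method = "average")
  target <- rowMeans(apply(m, 2L, sort))
  out <- apply(ranks, 2L, function(r) {
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}
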