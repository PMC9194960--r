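#' Gene-set collections
#'
#' A `gene_set_collection` holds named gene sets together with a category
#' label per set (e.g. the immune category a set belongs to, or "hallmark")
#' and a free-text provenance note. It is the container consumed by all
#' enrichment machinery ([lncres_score()], [gsva_scores()], [cell_scores()]).
#'
#' @param sets Named list of character vectors of gene identifiers. Every
#'   set must be non-empty and names must be unique.
#' @param category Optional named character vector (or single string
#'   recycled) giving a category label per set. Defaults to the set name
#'   itself.
#' @param provenance Free-text origin note.
#'
#' @return An object of class `gene_set_collection` with elements `sets`,
#'   `category` and `provenance`.
#' @export
#' @examples
#' gs <- gene_set_collection(list(A = c("g1", "g2"), B = "g3"))
#' length(gs$sets)
gene_set_collection <- function(sets, category = NULL, provenance = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list of character vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  sizes <- lengths(sets)
  if (any(sizes == 0L))
    stop("empty gene set(s): ", paste(names(sets)[sizes == 0L], collapse = ", "))
  if (is.null(category)) {
    category <- stats::setNames(names(sets), names(sets))
  } else if (length(category) == 1L && is.null(names(category))) {
    category <- stats::setNames(rep(as.character(category), length(sets)),
                                names(sets))
  } else {
    category <- stats::setNames(as.character(category[names(sets)]), names(sets))
    if (anyNA(category)) stop("'category' must cover every set name")
  }
  structure(list(sets = sets, category = category,
                 provenance = as.character(provenance)[1L]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%d categories), %d genes total\n",
              length(x$sets), length(unique(x$category)),
              length(unique(unlist(x$sets)))))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' kept as the set's category label.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  cats <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    genes <- f[-(1:2)]
    if (any(!nzchar(genes)))
      stop(sprintf("GMT parse error at line %d: empty gene field", i))
    nms[i] <- f[1L]
    cats[i] <- f[2L]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  gene_set_collection(sets, category = stats::setNames(cats, nms),
                      provenance = path)
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]; the category label is written into the
#' description field, so `read_gmt(write_gmt(x, p))` restores sets and
#' categories exactly (up to within-set gene order, which is preserved).
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$category[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write GMT file: ", path)
  invisible(path)
}

#' Canonical immune category labels
#'
#' The 17 curated immune gene-list categories (ImmPort-style: interferons,
#' interferon receptors, cytokines, ...) used to label the immune gene-set
#' collection. The count (17) is normative for the analysis; the labels are
#' cosmetic.
#'
#' @return Character vector of length 17.
#' @export
immune_category_names <- function() {
  c("Antigen_Processing_and_Presentation",
    "Antimicrobials",
    "BCR_Signaling_Pathway",
    "Chemokines",
    "Chemokine_Receptors",
    "Cytokines",
    "Cytokine_Receptors",
    "Interferons",
    "Interferon_Receptors",
    "Interleukins",
    "Interleukin_Receptors",
    "Natural_Killer_Cell_Cytotoxicity",
    "TCR_Signaling_Pathway",
    "TGFb_Family_Members",
    "TGFb_Family_Member_Receptors",
    "TNF_Family_Members",
    "TNF_Family_Member_Receptors")
}

#' Immune-cell population labels
#'
#' The 10 microenvironment cell populations scored by [cell_scores()].
#' The first four are the populations most often reported as differential
#' between inflammation subtypes.
#'
#' @return Character vector of length 10.
#' @export
cell_population_names <- function() {
  c("CD8_T_cells", "Cytotoxic_lymphocytes", "B_lineage",
    "Myeloid_dendritic_cells", "T_cells", "NK_cells",
    "Monocytic_lineage", "Neutrophils", "Endothelial_cells", "Fibroblasts")
}
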