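#' Enrich immune-related lncRNAs against pathway gene sets
#'
#' Identical machinery to [lncres_score()] run with a pathway collection
#' (e.g. the 50 hallmark sets) instead of the immune categories,
#' optionally restricted to an already-identified list of immune-related
#' lncRNAs.
#'
#' @param lnc_mat,mrna_mat Sample-aligned expression matrices.
#' @param pathways A [gene_set_collection()] of pathway sets.
#' @param lnc_ids Optional subset of lncRNAs to score (default: all rows).
#' @param ... Scoring parameters forwarded to [lncres_score()].
#' @return An `lncres_table` over (lncRNA, pathway) pairs.
#' @export
pathway_enrich <- function(lnc_mat, mrna_mat, pathways, lnc_ids = NULL,
                           ...) {
  if (!is.null(lnc_ids)) {
    missing <- setdiff(lnc_ids, rownames(lnc_mat))
    if (length(missing))
      stop("lnc id(s) not in the matrix: ", paste(missing, collapse = ", "))
    lnc_mat <- lnc_mat[lnc_ids, , drop = FALSE]
  }
  lncres_score(lnc_mat, mrna_mat, pathways, ...)
}

#' Build the bipartite lncRNA-pathway edge list
#'
#' Keeps significant records only, deduplicates, and restricts to the
#' `top_k` pathways with the most significant lncRNA partners (ties broken
#' by pathway name), or to an explicit `allow_list` of pathway names to
#' reproduce hand-picked selections. Edge weight is the lncRES value; the
#' sign records activation (+, positive enrichment) versus repression (-).
#'
#' @param records An `lncres_table`.
#' @param top_k Number of pathways to keep (default 5).
#' @param allow_list Optional explicit pathway names overriding `top_k`.
#' @return data.frame with `lnc`, `pathway`, `weight`, `sign`, ordered
#'   deterministically by pathway then lncRNA.
#' @export
build_network <- function(records, top_k = 5L, allow_list = NULL) {
  sig <- records[records$significant, c("lnc", "set", "lncres", "es"),
                 drop = FALSE]
  sig <- sig[!duplicated(paste(sig$lnc, sig$set, sep = "\r")), ,
             drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(lnc = character(), pathway = character(),
                      weight = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  if (is.null(allow_list)) {
    counts <- sort(table(sig$set), decreasing = TRUE)
    ord <- order(-as.integer(counts), names(counts), method = "radix")
    keep_paths <- names(counts)[ord][seq_len(min(top_k, length(counts)))]
  } else {
    keep_paths <- allow_list
  }
  sig <- sig[sig$set %in% keep_paths, , drop = FALSE]
  out <- data.frame(lnc = sig$lnc, pathway = sig$set, weight = sig$lncres,
                    sign = ifelse(sig$es >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pathway, out$lnc, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a lncRNA-pathway network
#'
#' SIF: one `lnc<TAB>interacts<TAB>pathway` line per edge. GraphML:
#' written through igraph with `weight` and `sign` edge attributes and a
#' `type` vertex attribute (`lnc` / `pathway`), so any standard graph
#' library re-reads it. The empty network produces a valid empty document
#' in both formats.
#'
#' @param edges Edge list from [build_network()].
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(if (nrow(edges)) paste(edges$lnc, "interacts", edges$pathway,
                                      sep = "\t") else character(),
               path)
  } else {
    g <- network_igraph(edges)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an edge list to a typed bipartite igraph object
#'
#' @param edges Edge list from [build_network()].
#' @return An igraph graph with vertex attribute `type` and edge
#'   attributes `weight` and `sign`.
#' @export
network_igraph <- function(edges) {
  verts <- data.frame(
    name = c(unique(edges$lnc), unique(edges$pathway)),
    type = rep(c("lnc", "pathway"),
               c(length(unique(edges$lnc)), length(unique(edges$pathway)))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    edges[, c("lnc", "pathway", "weight", "sign"), drop = FALSE],
    directed = FALSE, vertices = verts)
}
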