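#' Default pipeline configuration
#'
#' Nested list with one block per stage. Every parameter the source
#' protocol prints is a default here (lncRES cutoff 0.995, FDR cutoff
#' 0.05, consensus reps 1000 / pItem 0.8 / pFeature 1 / euclidean);
#' everything the protocol leaves open is an explicit documented key.
#' Configurations are stored/read as JSON (see [read_config()]).
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    io = list(min_iqr = 0, quantile_normalize = FALSE),
    de = list(alpha = 0.05, lfc = 1, moderated = TRUE),
    lncres = c(lncres_params(), list(seed = 1L)),
    network = list(top_k = 5L),
    subtype = list(k = "auto", k_range = c(2L, 6L), reps = 1000L,
                   p_item = 0.8, p_feature = 1, linkage = "average",
                   top_n = 50L, min_features = 5L, seed = 1L),
    profile = list(tau = 1, alpha = 0.05, test = "wilcoxon",
                   gsva_method = "mx.diff"),
    synth = unclass(synth_config())
  )
}

#' Read and validate a pipeline configuration
#'
#' JSON file with the [default_config()] structure; missing keys take
#' their defaults, unknown keys are rejected by name.
#'
#' @param path Path to a JSON config, or `NULL` for the defaults.
#' @return Validated nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_checked(cfg, user, "config")
}

merge_checked <- function(base, user, where) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s) under '", where, "': ",
         paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_checked(base[[nm]], as.list(user[[nm]]),
                                  paste(where, nm, sep = "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages in workflow order. `simulate` writes the
#' synthetic fixture; each analysis stage reads its inputs from `outdir`
#' (erroring with the name of the missing prior stage) and writes TSV/JSON
#' artifacts plus an entry in `manifest.json`. `all` chains every stage.
#' With fixed config and seeds, reruns reproduce the analysis tables
#' byte-identically.
#'
#' Stage artifacts: `simulate` the fixture files; `de` `de_mrna.tsv` /
#' `de_lnc.tsv`; `lncres` `lncres_records.tsv`, `immune_lnc.txt`,
#' `venn.json`; `network` `network_edges.tsv`, `network.sif`,
#' `network.graphml`; `subtype` `consensus_k*.tsv`, `subtype_labels.tsv`,
#' `pca.tsv`, `top_mrna.tsv`, `top_lnc.tsv`; `profile` `gsva_scores.tsv`,
#' `cell_scores.tsv`, `subtype_tests.tsv`.
#'
#' @param stage One of `simulate`, `de`, `lncres`, `network`, `subtype`,
#'   `profile`, `all`.
#' @param config Configuration list (see [read_config()]) or a path to a
#'   JSON config file.
#' @param outdir Output directory (created if needed).
#' @param seed Optional override of the seeds in the config.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "de", "lncres",
                                   "network", "subtype", "profile"),
                         config = default_config(), outdir, seed = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_config(config)
  config <- merge_checked(default_config(), config, "config")
  if (!is.null(seed)) {
    config$synth$seed <- as.integer(seed)
    config$synth$structure_seed <- as.integer(seed)
    config$lncres$seed <- as.integer(seed)
    config$subtype$seed <- as.integer(seed)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stages <- if (stage == "all")
    c("simulate", "de", "lncres", "network", "subtype", "profile")
  else stage
  manifest <- read_manifest(outdir)
  manifest$config <- config
  manifest$package_version <- as.character(utils::packageVersion("lncImmNet"))
  for (st in stages) {
    files <- switch(st,
      simulate = stage_simulate(config, outdir),
      de = stage_de(config, outdir),
      lncres = stage_lncres(config, outdir),
      network = stage_network(config, outdir),
      subtype = stage_subtype(config, outdir),
      profile = stage_profile(config, outdir))
    manifest$stages[[st]] <- files
    message("[", st, "] ", length(files$files), " file(s) written",
            if (!is.null(files$counts))
              paste0(" (", paste(sprintf("%s=%s", names(files$counts),
                                         files$counts), collapse = ", "),
                     ")") else "")
  }
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE)
  else list(stages = list())
}

require_stage <- function(outdir, file, prior) {
  p <- file.path(outdir, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run the '", prior,
         "' stage first")
  p
}

load_inputs <- function(config, outdir) {
  fx <- read_fixture(dirname(require_stage(outdir,
                                           "fixture/design.tsv",
                                           "simulate")))
  fx$bundle <- preclean(fx$bundle, min_iqr = config$io$min_iqr,
                        quantile_normalize = config$io$quantile_normalize)
  fx
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

stage_simulate <- function(config, outdir) {
  cfg <- do.call(synth_config, config$synth[setdiff(names(config$synth),
                                                    character(0))])
  sim <- generate_bundle(cfg)
  files <- write_fixture(sim, file.path(outdir, "fixture"),
                         write_cell_markers = TRUE)
  list(files = files,
       counts = list(lnc = nrow(sim$bundle$lnc),
                     mrna = nrow(sim$bundle$mrna),
                     samples = ncol(sim$bundle$lnc)))
}

stage_de <- function(config, outdir) {
  fx <- load_inputs(config, outdir)
  grp <- fx$bundle$design$condition
  tab_m <- de_analysis(fx$bundle$mrna, grp, alpha = config$de$alpha,
                       lfc = config$de$lfc,
                       moderated = config$de$moderated)
  tab_l <- de_analysis(fx$bundle$lnc, grp, alpha = config$de$alpha,
                       lfc = config$de$lfc,
                       moderated = config$de$moderated)
  f1 <- write_table_tsv(tab_m, file.path(outdir, "de_mrna.tsv"))
  f2 <- write_table_tsv(tab_l, file.path(outdir, "de_lnc.tsv"))
  list(files = c(f1, f2),
       counts = list(de_mrna = sum(tab_m$significant),
                     de_lnc = sum(tab_l$significant)))
}

stage_lncres <- function(config, outdir) {
  de_path <- require_stage(outdir, "de_lnc.tsv", "de")
  fx <- load_inputs(config, outdir)
  pr <- config$lncres
  tab <- lncres_score(fx$bundle$lnc, fx$bundle$mrna, fx$immune_sets,
                      method = pr$method, p_min = pr$p_min,
                      exponent = pr$exponent,
                      min_set_size = pr$min_set_size, nperm = pr$nperm,
                      lncres_cut = pr$lncres_cut, fdr_cut = pr$fdr_cut,
                      fdr_scope = pr$fdr_scope,
                      seed = pr$seed)
  imm <- immune_lnc_ids(tab)
  f1 <- write_table_tsv(tab, file.path(outdir, "lncres_records.tsv"))
  f2 <- file.path(outdir, "immune_lnc.txt")
  writeLines(imm, f2)
  de_tab <- utils::read.delim(de_path, stringsAsFactors = FALSE)
  de_ids <- de_tab$gene[de_tab$significant]
  venn <- intersect_with_de(imm, de_ids)
  f3 <- file.path(outdir, "venn.json")
  jsonlite::write_json(venn, f3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(files = c(f1, f2, f3),
       counts = list(immune_lnc = length(imm), de_lnc = length(de_ids),
                     overlap = venn$n_overlap))
}

stage_network <- function(config, outdir) {
  fx <- load_inputs(config, outdir)
  rec_path <- require_stage(outdir, "lncres_records.tsv", "lncres")
  tab <- utils::read.delim(rec_path, stringsAsFactors = FALSE)
  tab$significant <- as.logical(tab$significant)
  edges <- build_network(tab, top_k = config$network$top_k)
  f1 <- write_table_tsv(edges, file.path(outdir, "network_edges.tsv"))
  f2 <- export_network(edges, file.path(outdir, "network.sif"), "sif")
  f3 <- export_network(edges, file.path(outdir, "network.graphml"),
                       "graphml")
  list(files = c(f1, f2, f3), counts = list(edges = nrow(edges)))
}

stage_subtype <- function(config, outdir) {
  fx <- load_inputs(config, outdir)
  imm_path <- require_stage(outdir, "immune_lnc.txt", "lncres")
  de_path <- require_stage(outdir, "de_lnc.tsv", "de")
  imm <- readLines(imm_path)
  de_tab <- utils::read.delim(de_path, stringsAsFactors = FALSE)
  de_ids <- de_tab$gene[de_tab$significant]
  feats <- intersect(imm, de_ids)
  if (length(feats) < config$subtype$min_features) {
    # too few immune-related DElncRNAs to cluster on: widen to the union
    # so the stage stays runnable on weak or small-cohort signal
    feats <- union(imm, de_ids)
  }
  feats <- intersect(feats, rownames(fx$bundle$lnc))
  if (length(feats) < 2L)
    stop("fewer than 2 clustering features available")
  pulp <- fx$bundle$design$sample_id[fx$bundle$design$condition ==
                                       "pulpitis"]
  mat <- fx$bundle$lnc[feats, pulp, drop = FALSE]
  sc <- config$subtype
  k_range <- seq(sc$k_range[1], min(sc$k_range[2], length(pulp) - 1L))
  res <- consensus_cluster(mat, k_range = k_range, reps = sc$reps,
                           p_item = sc$p_item, p_feature = sc$p_feature,
                           linkage = sc$linkage,
                           final_k = if (identical(sc$k, "auto")) NULL
                           else as.integer(sc$k),
                           seed = sc$seed)
  files <- character()
  for (ks in names(res$consensus)) {
    f <- file.path(outdir, paste0("consensus_k", ks, ".tsv"))
    utils::write.table(res$consensus[[ks]], f, sep = "\t", quote = FALSE)
    files <- c(files, f)
  }
  lab_df <- data.frame(sample_id = names(res$labels),
                       subtype = unname(res$labels))
  files <- c(files, write_table_tsv(lab_df,
                                    file.path(outdir,
                                              "subtype_labels.tsv")))
  emb <- pca_embed(mat)
  pca_df <- data.frame(sample_id = rownames(emb$scores),
                       emb$scores[, seq_len(min(2L, ncol(emb$scores))),
                                  drop = FALSE])
  files <- c(files, write_table_tsv(pca_df, file.path(outdir, "pca.tsv")))
  sde <- subtype_de(fx$bundle, res$labels, top_n = sc$top_n,
                    alpha = config$de$alpha, lfc = 0)
  files <- c(files,
             write_table_tsv(sde$mrna$top, file.path(outdir,
                                                     "top_mrna.tsv")),
             write_table_tsv(sde$lnc$top, file.path(outdir,
                                                    "top_lnc.tsv")))
  list(files = files,
       counts = list(selected_k = res$selected_k,
                     features = length(feats)))
}

stage_profile <- function(config, outdir) {
  fx <- load_inputs(config, outdir)
  lab_path <- require_stage(outdir, "subtype_labels.tsv", "subtype")
  lab_df <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
  labels <- stats::setNames(lab_df$subtype, lab_df$sample_id)
  pulp_expr <- fx$bundle$mrna[, names(labels), drop = FALSE]
  pc <- config$profile
  gs <- gsva_scores(pulp_expr, fx$immune_sets, tau = pc$tau,
                    method = pc$gsva_method)
  files <- write_table_tsv(data.frame(set = rownames(gs), gs,
                                      check.names = FALSE),
                           file.path(outdir, "gsva_scores.tsv"))
  tests <- compare_subtypes(gs, labels, class_label = "pathway",
                            alpha = pc$alpha, test = pc$test)
  if (!is.null(fx$cell_markers)) {
    cs <- cell_scores(pulp_expr, fx$cell_markers)
    files <- c(files,
               write_table_tsv(data.frame(population = rownames(cs), cs,
                                          check.names = FALSE),
                               file.path(outdir, "cell_scores.tsv")))
    tests <- rbind(tests,
                   compare_subtypes(cs, labels, class_label = "cell",
                                    alpha = pc$alpha, test = pc$test))
  }
  files <- c(files, write_table_tsv(tests,
                                    file.path(outdir,
                                              "subtype_tests.tsv")))
  list(files = files,
       counts = list(significant_features = sum(tests$significant)))
}
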