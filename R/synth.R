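#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a latent co-expression factor per driven immune set (so one
#' lncRNA coherently drives an entire set, which is what the lncRES
#' statistic detects), two-group mean shifts for differential genes, and
#' planted immune subtypes within the pulpitis cohort. Defaults mirror a
#' small inflamed-pulp microarray cohort (5 normal / 7 pulpitis samples)
#' with gene counts scaled down (300 lncRNAs, 2000 mRNAs) from the ~10698 /
#' ~17867 of the full arrays.
#'
#' @param n_normal,n_pulpitis Samples per condition.
#' @param n_mrna,n_lnc Gene counts.
#' @param n_immune_sets Number of immune categories (default 17).
#' @param genes_per_set mRNAs per immune set (sets are disjoint).
#' @param n_planted_lnc Number of lncRNAs that drive an immune set through
#'   a latent factor.
#' @param rho Target population Pearson correlation between a planted
#'   lncRNA and each member mRNA of its set, in `[0, 1)`. Feasibility
#'   requires `rho^2 * (1 + noise_sd^2) < 1` under the unit-variance latent
#'   factor model.
#' @param de_frac Fraction of genes given a two-group mean shift.
#' @param de_effect Size of that shift (log2 units), random sign.
#' @param noise_sd Residual standard deviation (log2 units).
#' @param n_subtypes Planted immune subtypes within pulpitis (default 2).
#' @param subtype_effect Within-pulpitis shift (log2 units) applied to the
#'   subtype-marker immune sets, the subtype-marker lncRNAs and the
#'   differential cell populations of the designated subtype's samples.
#'   Set to 0 for a subtype-free world.
#' @param marker_sets_per_subtype Immune sets acting as expression programs
#'   of each subtype (their member mRNAs receive the subtype shift).
#' @param n_marker_lnc_per_subtype Subtype-marker lncRNAs planted per
#'   subtype. These are separate from the co-expression drivers: pure
#'   noise plus shift, so their within-subtype spread is exactly
#'   `noise_sd` (see the methods vignette for why).
#' @param n_cell_populations,markers_per_population Immune-cell marker sets
#'   emitted alongside the bundle (default 10 populations x 8 markers).
#' @param baseline Baseline log2 expression level.
#' @param dataset Cohort tag written into the design table.
#' @param seed Integer RNG seed for the noise draws.
#' @param structure_seed Seed for the planted structure (which lncRNAs
#'   drive which sets, which genes are differential, subtype membership).
#'   Defaults to `seed`; two configs sharing `structure_seed` but
#'   differing in `seed` share a GroundTruth while having independent
#'   noise, which is how the replication cohort is made.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_normal = 5L, n_pulpitis = 7L,
                         n_mrna = 2000L, n_lnc = 300L,
                         n_immune_sets = 17L, genes_per_set = 100L,
                         n_planted_lnc = 20L, rho = 0.8,
                         de_frac = 0.1, de_effect = 2, noise_sd = 0.5,
                         n_subtypes = 2L, subtype_effect = 1.5,
                         marker_sets_per_subtype = 2L,
                         n_marker_lnc_per_subtype = 6L,
                         n_cell_populations = 10L,
                         markers_per_population = 8L,
                         baseline = 8, dataset = "cohort_a",
                         seed = 1L, structure_seed = NULL) {
  cfg <- list(n_normal = as.integer(n_normal),
              n_pulpitis = as.integer(n_pulpitis),
              n_mrna = as.integer(n_mrna), n_lnc = as.integer(n_lnc),
              n_immune_sets = as.integer(n_immune_sets),
              genes_per_set = as.integer(genes_per_set),
              n_planted_lnc = as.integer(n_planted_lnc), rho = rho,
              de_frac = de_frac, de_effect = de_effect, noise_sd = noise_sd,
              n_subtypes = as.integer(n_subtypes),
              subtype_effect = subtype_effect,
              marker_sets_per_subtype = as.integer(marker_sets_per_subtype),
              n_marker_lnc_per_subtype = as.integer(n_marker_lnc_per_subtype),
              n_cell_populations = as.integer(n_cell_populations),
              markers_per_population = as.integer(markers_per_population),
              baseline = baseline, dataset = as.character(dataset),
              seed = as.integer(seed),
              structure_seed = as.integer(
                if (is.null(structure_seed)) seed else structure_seed))
  counts <- c("n_normal", "n_pulpitis", "n_mrna", "n_lnc", "n_immune_sets",
              "genes_per_set", "n_subtypes")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop("configuration error: ", nm, " must be >= 1")
  if (cfg$n_planted_lnc < 0L || cfg$n_planted_lnc > cfg$n_lnc)
    stop("configuration error: need 0 <= n_planted_lnc <= n_lnc")
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop("configuration error: need 0 <= rho < 1")
  if (cfg$noise_sd < 0 || cfg$de_frac < 0 || cfg$de_frac > 1)
    stop("configuration error: noise_sd >= 0 and de_frac in [0,1] required")
  if (cfg$genes_per_set * cfg$n_immune_sets > cfg$n_mrna)
    stop("configuration error: genes_per_set * n_immune_sets exceeds n_mrna")
  if (cfg$rho > 0 && cfg$noise_sd > 0 &&
      cfg$rho^2 * (1 + cfg$noise_sd^2) >= 1)
    stop("configuration error: rho^2 * (1 + noise_sd^2) must be < 1 ",
         "for the latent-factor loading to exist")
  n_markers <- cfg$n_cell_populations * cfg$markers_per_population
  pool <- cfg$n_mrna - cfg$genes_per_set * cfg$n_immune_sets
  if (n_markers > pool)
    stop("configuration error: cell-marker genes exceed the non-set mRNA pool")
  if (round(cfg$de_frac * cfg$n_mrna) > pool - n_markers)
    stop("configuration error: differential mRNAs exceed the free mRNA pool")
  if (cfg$subtype_effect != 0 &&
      cfg$marker_sets_per_subtype * cfg$n_subtypes > cfg$n_immune_sets)
    stop("configuration error: marker sets exceed n_immune_sets")
  if (cfg$n_subtypes > 1L && cfg$n_pulpitis < 2L * cfg$n_subtypes)
    warning("fewer than 2 pulpitis samples per subtype", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

#' Default replication-cohort configuration
#'
#' Same planted structure as a given config (shared `structure_seed`) but a
#' 6 normal / 6 pulpitis design and independent noise, emulating an
#' external validation dataset.
#'
#' @param cfg A [synth_config()] for the discovery cohort.
#' @param seed Noise seed for the replication cohort.
#' @return A `synth_config`.
#' @export
replication_config <- function(cfg, seed = cfg$seed + 1000L) {
  stopifnot(inherits(cfg, "synth_config"))
  cfg$n_normal <- 6L
  cfg$n_pulpitis <- 6L
  cfg$dataset <- "cohort_b"
  cfg$seed <- as.integer(seed)
  cfg
}

#' Generate a synthetic expression bundle with known ground truth
#'
#' Planted structure, drawn from `structure_seed`:
#' * immune sets: `n_immune_sets` disjoint blocks of `genes_per_set` mRNAs,
#'   labelled with the canonical immune category names;
#' * planted lncRNAs assigned round-robin to sets; each driven set `k` has
#'   one latent factor `L_k ~ N(0,1)` per sample; a driver lncRNA is
#'   `baseline + L_k + eps(noise_sd)` and each member mRNA is
#'   `baseline + a * L_k + shifts + eps(noise_sd)` with
#'   `a = rho * noise_sd / sqrt(1 - rho^2 * (1 + noise_sd^2))` chosen so the
#'   population lncRNA-member correlation equals `rho` exactly
#'   (when `noise_sd = 0` the loading is 1 and sample correlations are
#'   exactly 1);
#' * differential genes: a random sign times `de_effect` added to pulpitis
#'   samples, mRNA shifts drawn only from the free (non-set, non-marker)
#'   pool so the enrichment null stays clean;
#' * subtypes: pulpitis samples assigned round-robin; each subtype's marker
#'   immune sets, marker lncRNAs and differential cell populations receive
#'   `subtype_effect` in that subtype's samples only.
#'
#' Same config (including seeds) gives byte-identical output.
#'
#' @param config A [synth_config()].
#' @return List with `bundle` ([expression_bundle()]), `immune_sets` and
#'   `cell_markers` ([gene_set_collection()]s) and `truth` (ground-truth
#'   list: `planted_lnc_ids`, `lnc_to_set`, `de_gene_ids`, `de_table`,
#'   `subtype_labels`, `marker_lnc_ids`, `marker_sets`,
#'   `diff_cell_populations`).
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lnc))
  mrna_ids <- sprintf("MRNA%05d", seq_len(cfg$n_mrna))
  set_names <- make.unique(rep_len(immune_category_names(),
                                   cfg$n_immune_sets), sep = "_")
  pop_names <- make.unique(rep_len(cell_population_names(),
                                   cfg$n_cell_populations), sep = "_")
  samples <- c(sprintf("%s_normal_%02d", cfg$dataset, seq_len(cfg$n_normal)),
               sprintf("%s_pulpitis_%02d", cfg$dataset,
                       seq_len(cfg$n_pulpitis)))
  condition <- rep(c("normal", "pulpitis"), c(cfg$n_normal, cfg$n_pulpitis))
  n_samp <- length(samples)
  is_pulp <- condition == "pulpitis"

  # ---- planted structure (structure_seed) --------------------------------
  structure <- withr::with_seed(cfg$structure_seed, {
    members <- lapply(seq_len(cfg$n_immune_sets), function(k) {
      mrna_ids[((k - 1L) * cfg$genes_per_set + 1L):(k * cfg$genes_per_set)]
    })
    names(members) <- set_names
    free_pool <- mrna_ids[-seq_len(cfg$n_immune_sets * cfg$genes_per_set)]
    marker_genes <- if (cfg$n_cell_populations > 0L) {
      picked <- sample(free_pool,
                       cfg$n_cell_populations * cfg$markers_per_population)
      split(picked, rep(pop_names, each = cfg$markers_per_population))[pop_names]
    } else list()
    free_pool <- setdiff(free_pool, unlist(marker_genes))
    planted <- if (cfg$n_planted_lnc > 0L)
      sort(sample(lnc_ids, cfg$n_planted_lnc)) else character()
    lnc_to_set <- stats::setNames(
      set_names[((seq_along(planted) - 1L) %% cfg$n_immune_sets) + 1L],
      planted)
    n_de_m <- round(cfg$de_frac * cfg$n_mrna)
    de_mrna <- if (n_de_m > 0L) sample(free_pool, n_de_m) else character()
    n_de_l <- round(cfg$de_frac * cfg$n_lnc)
    de_lnc <- if (n_de_l > 0L) sample(lnc_ids, n_de_l) else character()
    marker_lnc <- list()
    marker_sets <- list()
    if (cfg$subtype_effect != 0 && cfg$n_subtypes > 1L) {
      avail <- setdiff(lnc_ids, planted)
      # subtype programs live in the sets with the fewest co-expression
      # drivers, so the subtype shift is not drowned by latent variance
      driver_counts <- as.integer(table(factor(lnc_to_set,
                                               levels = set_names)))
      set_order <- set_names[order(driver_counts, seq_along(set_names))]
      for (s in seq_len(cfg$n_subtypes)) {
        marker_lnc[[s]] <- sort(sample(avail, cfg$n_marker_lnc_per_subtype))
        avail <- setdiff(avail, marker_lnc[[s]])
        marker_sets[[s]] <- set_order[((s - 1L) *
                                         cfg$marker_sets_per_subtype +
                                         1L):(s * cfg$marker_sets_per_subtype)]
      }
      de_lnc <- union(de_lnc, unlist(marker_lnc))
    }
    de_sign <- stats::setNames(sample(c(-1, 1), length(de_mrna) +
                                        length(de_lnc), replace = TRUE),
                               c(de_mrna, de_lnc))
    list(members = members, marker_genes = marker_genes, planted = planted,
         lnc_to_set = lnc_to_set, de_mrna = de_mrna, de_lnc = de_lnc,
         de_sign = de_sign, marker_lnc = marker_lnc,
         marker_sets = marker_sets)
  })

  subtype <- integer(0)
  if (cfg$n_subtypes > 1L) {
    subtype <- ((seq_len(cfg$n_pulpitis) - 1L) %% cfg$n_subtypes) + 1L
  } else if (cfg$n_pulpitis > 0L) {
    subtype <- rep(1L, cfg$n_pulpitis)
  }
  names(subtype) <- samples[is_pulp]

  # latent loading solving cor(lnc, member) = rho under unit-variance latent
  loading <- if (cfg$rho == 0) 0 else if (cfg$noise_sd == 0) 1 else {
    c2 <- cfg$rho^2 * (1 + cfg$noise_sd^2)
    cfg$rho * cfg$noise_sd * sqrt(1 + cfg$noise_sd^2) / sqrt(1 - c2)
  }

  # ---- expression draws (seed) -------------------------------------------
  mats <- withr::with_seed(cfg$seed, {
    mrna <- matrix(stats::rnorm(cfg$n_mrna * n_samp, 0, cfg$noise_sd),
                   cfg$n_mrna, n_samp, dimnames = list(mrna_ids, samples))
    lnc <- matrix(stats::rnorm(cfg$n_lnc * n_samp, 0, cfg$noise_sd),
                  cfg$n_lnc, n_samp, dimnames = list(lnc_ids, samples))
    driven_sets <- unique(structure$lnc_to_set)
    latents <- matrix(stats::rnorm(length(driven_sets) * n_samp),
                      length(driven_sets), n_samp,
                      dimnames = list(driven_sets, samples))
    for (set in driven_sets) {
      L <- latents[set, ]
      drivers <- names(structure$lnc_to_set)[structure$lnc_to_set == set]
      lnc[drivers, ] <- sweep(lnc[drivers, , drop = FALSE], 2L, L, "+")
      mem <- structure$members[[set]]
      mrna[mem, ] <- sweep(mrna[mem, , drop = FALSE], 2L, loading * L, "+")
    }
    list(mrna = mrna, lnc = lnc)
  })
  mrna <- mats$mrna + cfg$baseline
  lnc <- mats$lnc + cfg$baseline

  # two-group shifts
  for (g in structure$de_mrna)
    mrna[g, is_pulp] <- mrna[g, is_pulp] +
      structure$de_sign[[g]] * cfg$de_effect
  for (g in structure$de_lnc)
    lnc[g, is_pulp] <- lnc[g, is_pulp] +
      structure$de_sign[[g]] * cfg$de_effect

  # subtype shifts (pulpitis samples of the designated subtype only)
  diff_pops <- character()
  if (cfg$subtype_effect != 0 && cfg$n_subtypes > 1L) {
    n_diff <- min(4L, cfg$n_cell_populations)
    diff_pops <- pop_names[seq_len(n_diff)]
    for (s in seq_len(cfg$n_subtypes)) {
      cols <- names(subtype)[subtype == s]
      genes <- unlist(structure$members[structure$marker_sets[[s]]])
      mrna[genes, cols] <- mrna[genes, cols] + cfg$subtype_effect
      lnc[structure$marker_lnc[[s]], cols] <-
        lnc[structure$marker_lnc[[s]], cols] + cfg$subtype_effect
      if (s == 1L && length(diff_pops)) {
        pg <- unlist(structure$marker_genes[diff_pops])
        mrna[pg, cols] <- mrna[pg, cols] + cfg$subtype_effect
      }
    }
  }

  design <- data.frame(sample_id = samples, condition = condition,
                       dataset = cfg$dataset, stringsAsFactors = FALSE)
  bundle <- expression_bundle(lnc, mrna, design,
                              require_groups = cfg$n_normal >= 2L &&
                                cfg$n_pulpitis >= 2L)
  immune_sets <- gene_set_collection(
    structure$members,
    provenance = sprintf("synthetic immune categories (%s, seed %d)",
                         cfg$dataset, cfg$structure_seed))
  cell_markers <- if (length(structure$marker_genes)) {
    gene_set_collection(structure$marker_genes,
                        category = "cell_population",
                        provenance = "synthetic stand-in marker sets")
  } else NULL
  truth <- list(
    planted_lnc_ids = structure$planted,
    lnc_to_set = structure$lnc_to_set,
    de_gene_ids = sort(c(structure$de_mrna, structure$de_lnc)),
    de_table = data.frame(
      gene_id = names(structure$de_sign),
      type = rep(c("mRNA", "lncRNA"),
                 c(length(structure$de_mrna), length(structure$de_lnc))),
      sign = unname(structure$de_sign), stringsAsFactors = FALSE),
    subtype_labels = subtype,
    marker_lnc_ids = structure$marker_lnc,
    marker_sets = structure$marker_sets,
    diff_cell_populations = diff_pops)
  list(bundle = bundle, immune_sets = immune_sets,
       cell_markers = cell_markers, truth = truth)
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits `lnc_expression.tsv`, `mrna_expression.tsv`, `design.tsv`,
#' `immune_sets.gmt` and `truth.json` (5 files; 6 when
#' `write_cell_markers = TRUE`). Round-trips losslessly through
#' [read_fixture()].
#'
#' @param sim Output of [generate_bundle()].
#' @param dir Target directory (created if needed).
#' @param write_cell_markers Also write `cell_markers.gmt`.
#' @return Character vector of the files written (the manifest).
#' @export
write_fixture <- function(sim, dir, write_cell_markers = FALSE) {
  if (!dir.exists(dir)) {
    ok <- try(dir.create(dir, recursive = TRUE), silent = TRUE)
    if (inherits(ok, "try-error") || !dir.exists(dir))
      stop("cannot create fixture directory: ", dir)
  }
  files <- c(lnc = file.path(dir, "lnc_expression.tsv"),
             mrna = file.path(dir, "mrna_expression.tsv"),
             design = file.path(dir, "design.tsv"),
             gmt = file.path(dir, "immune_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(sim$bundle$lnc, files[["lnc"]])
  write_expression_tsv(sim$bundle$mrna, files[["mrna"]])
  write_design_tsv(sim$bundle$design, files[["design"]])
  write_gmt(sim$immune_sets, files[["gmt"]])
  write_truth(sim$truth, files[["truth"]])
  if (write_cell_markers && !is.null(sim$cell_markers)) {
    mk <- file.path(dir, "cell_markers.gmt")
    write_gmt(sim$cell_markers, mk)
    files <- c(files, markers = mk)
  }
  unname(files)
}

write_truth <- function(truth, path) {
  out <- truth
  out$subtype_labels <- as.list(truth$subtype_labels)
  out$lnc_to_set <- as.list(truth$lnc_to_set)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON written by [write_fixture()]
#' @param path Path to `truth.json`.
#' @return Ground-truth list (see [generate_bundle()]).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$subtype_labels <- unlist(x$subtype_labels)
  x$lnc_to_set <- unlist(x$lnc_to_set)
  x$de_table <- as.data.frame(x$de_table, stringsAsFactors = FALSE)
  x$marker_lnc_ids <- lapply(x$marker_lnc_ids, as.character)
  x$marker_sets <- lapply(x$marker_sets, as.character)
  x
}
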