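#' Ranking recovery of planted essential genes
#'
#' Area under the ROC curve for recovering planted invasion-essential
#' genes by ranking gene scores from most depleted upward. Computed from
#' the Wilcoxon rank-sum statistic (ties counted half), so 1 means every
#' essential gene scores below every non-essential gene.
#'
#' @param scores Gene-score table from [gene_score()].
#' @param truth Truth table with `gene` and logical `essential` (as
#'   returned by [simulate_screen_counts()]).
#' @return AUROC in \[0, 1\].
#' @export
recovery_auroc <- function(scores, truth) {
  ess <- truth$essential[match(scores$gene, truth$gene)]
  if (any(is.na(ess))) stop("truth is missing genes present in scores")
  pos <- scores$score[ess]    # planted: expected negative
  neg <- scores$score[!ess]
  if (!length(pos) || !length(neg)) stop("need both classes in truth")
  w <- stats::wilcox.test(neg, pos, exact = FALSE)$statistic
  unname(w) / (length(pos) * length(neg))
}

stage_error <- function(stage, msg) {
  stop(sprintf("stage '%s': %s", stage, msg), call. = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the invasion-multiomics pipeline
#'
#' Orchestrates the stages — `simulate` (seeded synthetic inputs),
#' `screen` (guide counts to gene-level hit calls), `invasion` (device
#' mask to per-cell metrics and rule counts), `fractal` (tumor mask to
#' box-counting dimension), `omics` (paired differential abundance) — in
#' dependency order, writing every output as a new file under `out_dir`
#' and a `manifest.json` recording inputs, parameters, seeds, package
#' version, and per-stage summaries. Rerunning with the same config
#' reproduces all outputs bit-identically. Later stages read the files
#' written by `simulate` unless the config points at user-supplied inputs,
#' and fail with an error naming the missing stage otherwise.
#'
#' @param config Nested list (or path to a JSON file) with optional
#'   blocks `simulate`, `screen`, `invasion`, `fractal`, `omics`; top
#'   level `seed` and `stages`. Unset parameters use the package
#'   defaults.
#' @param out_dir Output directory (created; must be empty or absent).
#' @return The manifest, invisibly.
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "demo_run")
#' mf <- run_pipeline(list(seed = 1, simulate = list(
#'   screen = list(n_genes = 60, guides_per_gene = 5,
#'                 n_nontargeting = 30, mean_depth = 200))), dir)
#' names(mf$stages)
#' }
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    stop("`out_dir` exists and is not empty")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "screen", "invasion",
                                 "fractal", "omics")
  manifest <- list(package = "invadeR",
                   version = as.character(utils::packageVersion("invadeR")),
                   seed = seed, config = config, stages = list())
  paths <- list()

  if ("simulate" %in% stages) {
    sim_cfg <- config$simulate %||% list()
    scr_args <- sim_cfg$screen %||% list()
    scr_args$seed <- scr_args$seed %||% seed
    scr <- simulate_screen_counts(do.call(screen_sim_config, scr_args))
    paths$counts <- file.path(out_dir, "guide_counts.tsv")
    write_guide_counts(scr, paths$counts)
    paths$truth <- file.path(out_dir, "screen_truth.json")
    jsonlite::write_json(scr$truth, paths$truth)

    ab_args <- sim_cfg$abundance %||% list()
    ab_args$seed <- ab_args$seed %||% (seed + 1L)
    pa <- simulate_paired_abundance(do.call(abundance_sim_config, ab_args))
    paths$abundance <- file.path(out_dir, "abundance.tsv")
    paths$pairs <- file.path(out_dir, "pairs.tsv")
    write_abundance(pa, paths$abundance, paths$pairs)
    paths$abundance_truth <- file.path(out_dir, "abundance_truth.json")
    jsonlite::write_json(pa$truth, paths$abundance_truth)

    dev_args <- sim_cfg$device %||% list(image_size = 256L, n_cells = 40L)
    dev_args$kind <- "device_field"
    dev_args$seed <- dev_args$seed %||% (seed + 2L)
    paths$device_mask <- file.path(out_dir, "device_mask.png")
    write_mask(do.call(simulate_mask, dev_args), paths$device_mask)

    tum_args <- sim_cfg$tumor %||% list(image_size = 256L,
                                        branching_intensity = 2)
    tum_args$kind <- "branched_growth"
    tum_args$seed <- tum_args$seed %||% (seed + 3L)
    paths$tumor_mask <- file.path(out_dir, "tumor_mask.png")
    write_mask(do.call(simulate_mask, tum_args), paths$tumor_mask)

    manifest$stages$simulate <- list(
      seed = seed,
      n_guides = nrow(scr$guide_info),
      n_planted_essential = sum(scr$truth$essential),
      n_abundance_features = nrow(pa$abundance))
  }

  if ("screen" %in% stages) {
    counts_path <- config$screen$counts %||% paths$counts
    if (is.null(counts_path) || !file.exists(counts_path)) {
      stage_error("screen", "no guide counts; run 'simulate' first or set screen$counts")
    }
    scr <- read_guide_counts(counts_path)
    sp <- config$screen %||% list()
    fit <- score_screen(scr,
                        pseudocount = sp$pseudocount %||% 0.5,
                        score_threshold = sp$score_threshold %||% 1,
                        p_threshold = sp$p_threshold %||% 0.05)
    write_tsv(fit$guides, file.path(out_dir, "guide_fitness.tsv"))
    write_tsv(fit$genes, file.path(out_dir, "gene_scores.tsv"))
    write_tsv(fit$hits, file.path(out_dir, "screen_hits.tsv"))
    volcano <- data.frame(gene = fit$genes$gene, log2_fc = fit$genes$score,
                          neg_log10_p = -log10(fit$genes$p_value))
    write_tsv(volcano, file.path(out_dir, "screen_volcano.tsv"))
    pca <- screen_pca(scr)
    write_tsv(data.frame(sample = rownames(pca$scores),
                         pca$scores[, 1:2, drop = FALSE],
                         fraction = pca$sample_info$fraction),
              file.path(out_dir, "screen_pca.tsv"))
    smry <- list(n_genes = nrow(fit$genes), n_hits = nrow(fit$hits),
                 n_core_enriched = sum(fit$hits$direction == "core_enriched"))
    truth_path <- paths$truth
    if (!is.null(truth_path) && file.exists(truth_path)) {
      truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
      smry$recovery_auroc <- recovery_auroc(fit$genes, truth)
      hits_core <- fit$hits$gene[fit$hits$direction == "core_enriched"]
      smry$planted_recovered <- sum(truth$gene[truth$essential] %in% hits_core)
    }
    manifest$stages$screen <- smry
  }

  if ("invasion" %in% stages) {
    mask_path <- config$invasion$mask %||% paths$device_mask
    if (is.null(mask_path) || !file.exists(mask_path)) {
      stage_error("invasion", "no device mask; run 'simulate' first or set invasion$mask")
    }
    mask <- read_mask(mask_path)
    cells <- segment_cells(mask)
    det <- detect_detached(cells,
      radius_um = config$invasion$radius_um %||% 10,
      max_cell_area_um2 = config$invasion$max_cell_area_um2 %||% 500)
    inv <- classify_invasive(cells,
      threshold_um = config$invasion$threshold_um %||% 200)
    cells$detached <- cells$label %in% det$label
    cells$highly_invasive <- inv
    cells$morphology <- classify_morphology(cells)
    write_tsv(cells, file.path(out_dir, "cells.tsv"))
    manifest$stages$invasion <- list(
      n_cells = nrow(cells), n_detached = nrow(det),
      n_highly_invasive = sum(inv),
      n_elongated = sum(cells$morphology == "elongated"))
  }

  if ("fractal" %in% stages) {
    mask_path <- config$fractal$mask %||% paths$tumor_mask
    if (is.null(mask_path) || !file.exists(mask_path)) {
      stage_error("fractal", "no tumor mask; run 'simulate' first or set fractal$mask")
    }
    ff <- fractal_dimension(read_mask(mask_path),
                            mode = config$fractal$mode %||% "boundary")
    jsonlite::write_json(
      list(dimension = ff$dimension, fit_r2 = ff$fit_r2, mode = ff$mode),
      file.path(out_dir, "fractal.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(data.frame(box_size = ff$box_sizes, count = ff$box_counts),
              file.path(out_dir, "fractal_counts.tsv"))
    manifest$stages$fractal <- list(dimension = ff$dimension,
                                    fit_r2 = ff$fit_r2, mode = ff$mode)
  }

  if ("omics" %in% stages) {
    mat_path <- config$omics$matrix %||% paths$abundance
    pairs_path <- config$omics$pairs %||% paths$pairs
    if (is.null(mat_path) || !file.exists(mat_path) ||
        is.null(pairs_path) || !file.exists(pairs_path)) {
      stage_error("omics", "no abundance matrix; run 'simulate' first or set omics$matrix/pairs")
    }
    pa <- read_abundance(mat_path, pairs_path)
    diff <- paired_differential(pa)
    write_tsv(diff, file.path(out_dir, "diff_table.tsv"))
    top <- rank_top(diff, k = config$omics$top_k %||% 10L)
    write_tsv(top, file.path(out_dir, "top_enriched.tsv"))
    pca <- pca_scores(pa)
    write_tsv(data.frame(sample = rownames(pca$scores),
                         pca$scores[, 1:2, drop = FALSE],
                         fraction = pca$sample_info$fraction),
              file.path(out_dir, "omics_pca.tsv"))
    manifest$stages$omics <- list(
      n_features = nrow(diff),
      n_significant = sum(diff$p_adjusted <= 0.05, na.rm = TRUE),
      top_feature = top$feature[1])
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
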