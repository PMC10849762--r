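#' Pool replicates and normalize a screen to counts per million
#'
#' Replicate counts within each fraction are summed and the pooled
#' fraction is scaled to counts per million, so each fraction is analyzed
#' as a single condition.
#'
#' @param screen A `screen_counts` object (see
#'   [simulate_screen_counts()], [read_guide_counts()]).
#' @return A data frame with `guide_id`, `gene`, `is_nontargeting`,
#'   `cpm_core`, `cpm_invasive`; each CPM column sums to 1e6.
#' @export
pool_and_normalize <- function(screen) {
  stopifnot(inherits(screen, "screen_counts"))
  si <- screen$sample_info
  if (!all(c("core", "invasive") %in% si$fraction)) {
    stop("need at least one core and one invasive sample")
  }
  pooled <- vapply(c("core", "invasive"), function(fr) {
    rowSums(screen$counts[, si$sample[si$fraction == fr], drop = FALSE])
  }, numeric(nrow(screen$counts)))
  if (any(colSums(pooled) == 0)) {
    stop("a fraction has zero total counts; cannot normalize")
  }
  cpm <- sweep(pooled, 2, colSums(pooled), "/") * 1e6
  data.frame(screen$guide_info,
             cpm_core = cpm[, "core"],
             cpm_invasive = cpm[, "invasive"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-guide fitness scores
#'
#' Guide fitness is the log2 ratio of normalized invasive over core
#' abundance, referenced to the nontargeting controls by subtracting the
#' median raw fitness of nontargeting guides (so their centered median is
#' exactly 0). Negative fitness means the guide is depleted at the
#' invasive front — knockout of its gene disrupted invasion.
#'
#' @param norm Output of [pool_and_normalize()].
#' @param pseudocount CPM added to numerator and denominator; keeps
#'   zero-count guides finite.
#' @param center_nontargeting Subtract the nontargeting median
#'   (default TRUE). Skipped with a warning if the library has no
#'   nontargeting guides.
#' @return `norm` with columns `fitness_raw` and `fitness` added.
#' @export
guide_fitness <- function(norm, pseudocount = 0.5,
                          center_nontargeting = TRUE) {
  stopifnot(is.data.frame(norm),
            all(c("cpm_core", "cpm_invasive", "is_nontargeting") %in%
                  names(norm)))
  stop_if_not_scalar_number(pseudocount, "pseudocount", min = 0)
  raw <- log2((norm$cpm_invasive + pseudocount) /
              (norm$cpm_core + pseudocount))
  if (any(!is.finite(raw))) {
    stop("non-finite fitness; use a positive pseudocount for zero counts")
  }
  shift <- 0
  if (center_nontargeting) {
    if (!any(norm$is_nontargeting)) {
      warning("no nontargeting guides in library; skipping centering")
    } else {
      shift <- stats::median(raw[norm$is_nontargeting])
    }
  }
  out <- norm
  out$fitness_raw <- raw
  out$fitness <- raw - shift
  out
}

#' Gene-level scores from guide fitness
#'
#' The gene score is the median of its guides' fitness values (the gene's
#' log2 fold change, nontargeting-referenced when the fitness table was
#' centered); a two-sided one-sample t test asks whether the guides
#' deviate significantly from 0. By default the test runs on the raw
#' (uncentered) log2 ratios: subtracting the nontargeting median — a
#' noisy common reference — from every guide would shift all gene tests
#' together and miscalibrate their null, whereas the raw ratios are
#' already centered by the counts-per-million normalization. Genes with a
#' single guide keep their score but get an undefined p-value; when all
#' guide fitnesses of a gene are exactly equal the t statistic is
#' undefined and p is 1 for a zero score and NA otherwise.
#'
#' @param fitness Output of [guide_fitness()].
#' @param use_centered Run the deviation test on the
#'   nontargeting-centered fitness instead of the raw log2 ratios
#'   (default FALSE; the reported score is always the median of the
#'   centered values when centering was applied).
#' @return A data frame with `gene`, `score`, `p_value`, `n_guides`.
#' @export
gene_score <- function(fitness, use_centered = FALSE) {
  stopifnot(is.data.frame(fitness), "gene" %in% names(fitness))
  val_col <- if (use_centered || !"fitness_raw" %in% names(fitness))
    "fitness" else "fitness_raw"
  targeting <- fitness[!fitness$is_nontargeting & !is.na(fitness$gene), ]
  if (nrow(targeting) == 0) stop("no targeting guides to score")
  groups <- split(targeting[[val_col]], targeting$gene)
  score_groups <- split(targeting$fitness, targeting$gene)
  empty <- vapply(groups, length, 1L) == 0L
  if (any(empty)) {
    warning("excluding ", sum(empty), " gene(s) with no guides")
    groups <- groups[!empty]
    score_groups <- score_groups[!empty]
  }
  score <- vapply(score_groups, stats::median, numeric(1))
  p <- vapply(groups, function(v) {
    if (length(v) < 2) return(NA_real_)
    if (stats::sd(v) == 0) return(if (v[1] == 0) 1 else NA_real_)
    stats::t.test(v, mu = 0)$p.value
  }, numeric(1))
  data.frame(gene = names(groups), score = unname(score),
             p_value = unname(p),
             n_guides = unname(vapply(groups, length, 1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call invasion hits from gene scores
#'
#' Genes depleted in the invasive fraction (score at or below
#' `-score_threshold`, p at or below `p_threshold`) are called
#' `core_enriched` — invasion-essential candidates; the symmetric rule
#' gives `invasive_enriched`. Hits are sorted by p-value, then |score|.
#'
#' @param scores Output of [gene_score()].
#' @param score_threshold Positive log2-fold-change cutoff (default 1).
#' @param p_threshold p-value cutoff (default 0.05).
#' @return `scores` restricted to hits, with a `direction` column.
#' @export
call_hits <- function(scores, score_threshold = 1, p_threshold = 0.05) {
  stop_if_not_scalar_number(score_threshold, "score_threshold", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(p_threshold, "p_threshold", min = 0,
                            strict_min = TRUE)
  ok_p <- !is.na(scores$p_value) & scores$p_value <= p_threshold
  dir <- rep("neutral", nrow(scores))
  dir[ok_p & scores$score <= -score_threshold] <- "core_enriched"
  dir[ok_p & scores$score >= score_threshold] <- "invasive_enriched"
  hits <- scores[dir != "neutral", , drop = FALSE]
  hits$direction <- dir[dir != "neutral"]
  hits[order(hits$p_value, -abs(hits$score), hits$gene), , drop = FALSE]
}

#' Score a pooled invasion screen end to end
#'
#' Runs [pool_and_normalize()], [guide_fitness()], [gene_score()] and
#' [call_hits()] and returns a single fitted object.
#'
#' @inheritParams pool_and_normalize
#' @inheritParams guide_fitness
#' @inheritParams call_hits
#' @param use_centered Run the deviation test on centered fitness values
#'   (see [gene_score()]).
#' @return An object of class `screen_scores`: list with `guides` (guide
#'   fitness table), `genes` (gene score table), `hits`, and `params`.
#' @examples
#' sim <- simulate_screen_counts(screen_sim_config(n_genes = 60,
#'   guides_per_gene = 5, n_nontargeting = 30, mean_depth = 300, seed = 3))
#' fit <- score_screen(sim)
#' summary(fit)
#' @export
score_screen <- function(screen, pseudocount = 0.5,
                         center_nontargeting = TRUE, use_centered = FALSE,
                         score_threshold = 1, p_threshold = 0.05) {
  guides <- guide_fitness(pool_and_normalize(screen),
                          pseudocount = pseudocount,
                          center_nontargeting = center_nontargeting)
  genes <- gene_score(guides, use_centered = use_centered)
  hits <- call_hits(genes, score_threshold = score_threshold,
                    p_threshold = p_threshold)
  structure(list(guides = guides, genes = genes, hits = hits,
                 params = list(pseudocount = pseudocount,
                               center_nontargeting = center_nontargeting,
                               use_centered = use_centered,
                               score_threshold = score_threshold,
                               p_threshold = p_threshold)),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf("Pooled CRISPR screen: %d guides, %d genes scored\n",
              nrow(x$guides), nrow(x$genes)))
  cat(sprintf("Hits at |log2FC| >= %g, p <= %g: %d core-enriched, %d invasive-enriched\n",
              x$params$score_threshold, x$params$p_threshold,
              sum(x$hits$direction == "core_enriched"),
              sum(x$hits$direction == "invasive_enriched")))
  invisible(x)
}

#' @export
summary.screen_scores <- function(object, n = 10L, ...) {
  print(object)
  top <- utils::head(object$hits, n)
  if (nrow(top)) {
    cat("\nTop hits (sorted by p, then |score|):\n")
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Volcano plot of gene scores
#'
#' @param x A `screen_scores` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.screen_scores <- function(x, ...) {
  g <- x$genes
  hit <- g$gene %in% x$hits$gene
  graphics::plot(g$score, -log10(g$p_value),
                 xlab = expression(log[2] ~ "fold change (invasive/core)"),
                 ylab = expression(-log[10] ~ "p"),
                 col = ifelse(hit, "firebrick", "grey50"),
                 pch = 16, cex = 0.6, ...)
  graphics::abline(v = c(-1, 1) * x$params$score_threshold, lty = 3)
  graphics::abline(h = -log10(x$params$p_threshold), lty = 3)
  invisible(x)
}

#' Principal components of per-sample screen counts
#'
#' Projects per-sample log2 CPM profiles (feature-centered) onto their
#' principal components; separation of core and invasive samples on the
#' leading components indicates a reproducible invasion signature.
#'
#' @param screen A `screen_counts` object with at least 2 samples.
#' @param pseudocount CPM added before the log transform.
#' @return List with `scores` (samples x components), `var_explained`
#'   (fractions summing to <= 1), and `sample_info`.
#' @export
screen_pca <- function(screen, pseudocount = 0.5) {
  stopifnot(inherits(screen, "screen_counts"))
  if (ncol(screen$counts) < 2) stop("PCA needs at least 2 samples")
  cpm <- sweep(screen$counts, 2, colSums(screen$counts), "/") * 1e6
  logcpm <- log2(cpm + pseudocount)
  pc <- stats::prcomp(t(logcpm), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  list(scores = pc$x,
       var_explained = if (tot > 0) pc$sdev^2 / tot else 0 * pc$sdev,
       sample_info = screen$sample_info)
}
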