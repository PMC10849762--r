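#' Paired core-versus-invasive differential abundance
#'
#' For each feature, the fold change is the ratio of the invasive group
#' mean to the core group mean over paired units (optionally the mean of
#' per-pair ratios), and the p-value comes from a two-sided t test on
#' log2-transformed abundances — paired by unit by default, matching the
#' paired design in which every hydrogel device or patient contributes
#' both fractions. Adjusted p-values are Benjamini-Hochberg.
#'
#' @param pa A `paired_abundance` object (see
#'   [simulate_paired_abundance()], [read_abundance()]).
#' @param pseudo Pseudo-abundance added before log transform; default
#'   `1e-6 * median(abundance)` to guard zeros under a multiplicative
#'   noise model.
#' @param paired Use a paired t test (default) or unpaired.
#' @param fc_method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A data frame (`feature`, `fold_change`, `log2_fc`, `p_value`,
#'   `p_adjusted`, `direction`) sorted as the input features.
#' @export
paired_differential <- function(pa, pseudo = NULL, paired = TRUE,
                                fc_method = c("ratio_of_means",
                                              "mean_of_ratios")) {
  stopifnot(inherits(pa, "paired_abundance"))
  fc_method <- match.arg(fc_method)
  si <- pa$sample_info
  units <- intersect(si$unit[si$fraction == "core"],
                     si$unit[si$fraction == "invasive"])
  if (length(units) < 2) stop("need >= 2 complete core/invasive pairs")
  core_s <- si$sample[si$fraction == "core"][match(units,
              si$unit[si$fraction == "core"])]
  inv_s <- si$sample[si$fraction == "invasive"][match(units,
              si$unit[si$fraction == "invasive"])]
  x_core <- pa$abundance[, core_s, drop = FALSE]
  x_inv <- pa$abundance[, inv_s, drop = FALSE]
  if (is.null(pseudo)) pseudo <- 1e-6 * stats::median(pa$abundance)
  stop_if_not_scalar_number(pseudo, "pseudo", min = 0)

  fc <- if (fc_method == "ratio_of_means") {
    rowMeans(x_inv + pseudo) / rowMeans(x_core + pseudo)
  } else {
    rowMeans((x_inv + pseudo) / (x_core + pseudo))
  }
  la <- log2(x_inv + pseudo)
  lb <- log2(x_core + pseudo)
  p <- vapply(seq_len(nrow(la)), function(i) {
    a <- la[i, ]; b <- lb[i, ]
    if (paired && stats::sd(a - b) == 0) {
      return(if (all(a == b)) 1 else NA_real_)
    }
    if (!paired && stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else NA_real_)
    }
    stats::t.test(a, b, paired = paired)$p.value
  }, numeric(1))
  data.frame(feature = rownames(pa$abundance),
             fold_change = unname(fc),
             log2_fc = unname(log2(fc)),
             p_value = p,
             p_adjusted = bh_adjust(p),
             direction = ifelse(fc > 1, "up_invasive",
                                ifelse(fc < 1, "down_invasive", "flat")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top enriched features by fold change
#'
#' Ranks features by fold change (largest first) among those passing an
#' optional p-value cap; ties break by smaller p-value, then lexical
#' feature id.
#'
#' @param diff A differential table from [paired_differential()].
#' @param k Number of features to return (default 10).
#' @param p_cap Optional p-value ceiling applied before ranking.
#' @return The top `k` rows of `diff`.
#' @export
rank_top <- function(diff, k = 10L, p_cap = NULL) {
  k <- stop_if_not_count(k, "k")
  d <- diff
  if (!is.null(p_cap)) d <- d[!is.na(d$p_value) & d$p_value <= p_cap, ]
  ord <- order(-d$fold_change, d$p_value, d$feature)
  utils::head(d[ord, , drop = FALSE], k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a validating front end to
#' [stats::p.adjust()] with `method = "BH"`. NA p-values are carried
#' through.
#'
#' @param p_values Numeric vector in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, monotone in the input ranks and <= 1.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Median-of-ratios normalization with geometric-mean reference
#'
#' For each feature a geometric mean across samples is calculated
#' (features containing zeros are excluded from factor estimation), counts
#' are divided by that reference, and each sample's size factor is the
#' median of those ratios; normalized counts are the raw counts divided by
#' the sample's size factor.
#'
#' @param counts Non-negative matrix, features x samples (>= 2 samples).
#' @return List with `normalized` (matrix) and `size_factors` (one per
#'   sample).
#' @export
geomean_normalize <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2, all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no feature is zero-free; cannot estimate factors")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- exp(rowMeans(logc))
  sf <- apply(counts[pos, , drop = FALSE] / ref, 2, stats::median)
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotated set for over-representation in a hit list drawn
#' from a universe of measured identifiers: the p-value is the upper
#' hypergeometric tail P(X >= overlap); q-values are Benjamini-Hochberg.
#' Set members outside the universe are dropped (logged via a message).
#'
#' @param hits Character vector of hit identifiers (subset of universe).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of all measured identifiers.
#' @return Data frame per set: `set`, `n_set`, `n_hits`, `overlap`,
#'   `fold_enrichment`, `p_value`, `q_value`, sorted by p.
#' @export
ora_enrichment <- function(hits, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  stopifnot(is.list(sets), !is.null(names(sets)))
  n_univ <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    dropped <- setdiff(members, universe)
    if (length(dropped)) {
      message(sprintf("set '%s': dropping %d member(s) outside universe",
                      nm, length(dropped)))
    }
    members <- intersect(members, universe)
    m <- length(members)
    k <- length(intersect(hits, members))
    p <- if (m == 0) 1 else
      stats::phyper(k - 1, m, n_univ - m, n_hits, lower.tail = FALSE)
    fe <- if (m == 0 || n_hits == 0) NA_real_ else
      (k / n_hits) / (m / n_univ)
    data.frame(set = nm, n_set = m, n_hits = n_hits, overlap = k,
               fold_enrichment = fe, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out[order(out$p_value, out$set), , drop = FALSE]
}

#' Concordance of two fold-change profiles
#'
#' Pearson correlation of paired per-feature log2 fold changes (matched
#' by name) and the fraction of features whose changes strictly disagree
#' in sign, e.g. between a knockdown and a control line.
#'
#' @param fc_a,fc_b Named numeric vectors of log2 fold changes sharing
#'   >= 3 feature names.
#' @return List with `pearson_r`, `n_total`, `n_discordant`, and
#'   `pct_discordant` (percent, one decimal).
#' @export
concordance <- function(fc_a, fc_b) {
  if (!is.null(names(fc_a)) && !is.null(names(fc_b))) {
    shared <- intersect(names(fc_a), names(fc_b))
    fc_a <- fc_a[shared]; fc_b <- fc_b[shared]
  } else if (length(fc_a) != length(fc_b)) {
    stop("unnamed fold-change vectors must have equal length")
  }
  n <- length(fc_a)
  if (n < 3) stop("need >= 3 shared features")
  disc <- (fc_a > 0 & fc_b < 0) | (fc_a < 0 & fc_b > 0)
  list(pearson_r = stats::cor(fc_a, fc_b),
       n_total = n,
       n_discordant = sum(disc),
       pct_discordant = round(100 * sum(disc) / n, 1))
}

#' Metabolic subset of a differentially expressed gene list
#'
#' Intersects DEG identifiers with a metabolic-gene catalog (e.g. the
#' human metabolic atlas) and reports the percentage of DEGs that are
#' metabolic, rounded to the nearest integer.
#'
#' @param deg_ids Non-empty character vector of DEG identifiers.
#' @param catalog Character vector of catalog identifiers.
#' @return List with `subset` (intersection), `n_deg`, `n_metabolic`,
#'   and `pct` (integer percent).
#' @export
subset_metabolic <- function(deg_ids, catalog) {
  deg_ids <- unique(deg_ids)
  if (length(deg_ids) == 0) stop("empty DEG list")
  sub <- intersect(deg_ids, unique(catalog))
  list(subset = sub, n_deg = length(deg_ids), n_metabolic = length(sub),
       pct = as.integer(round(100 * length(sub) / length(deg_ids))))
}

#' Principal components of a paired abundance matrix
#'
#' Log2-transforms the abundances, centers features, and projects samples
#' onto principal components; separation of core and invasive samples
#' indicates distinct metabolic profiles.
#'
#' @param pa A `paired_abundance` object with >= 3 samples.
#' @param pseudo Pseudo-abundance before the log transform (default as in
#'   [paired_differential()]).
#' @return List with `scores`, `var_explained`, `sample_info`.
#' @export
pca_scores <- function(pa, pseudo = NULL) {
  stopifnot(inherits(pa, "paired_abundance"))
  if (ncol(pa$abundance) < 3) stop("PCA needs at least 3 samples")
  if (is.null(pseudo)) pseudo <- 1e-6 * stats::median(pa$abundance)
  lx <- log2(pa$abundance + pseudo)
  pc <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  list(scores = pc$x,
       var_explained = if (tot > 0) pc$sdev^2 / tot else 0 * pc$sdev,
       sample_info = pa$sample_info)
}
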