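make_pa <- function(mat, units = NULL) {
  n_pairs <- ncol(mat) / 2
  units <- units %||% sprintf("u%d", seq_len(n_pairs))
  samples <- c(paste0(units, "_core"), paste0(units, "_invasive"))
  colnames(mat) <- samples
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("f%03d", seq_len(nrow(mat)))
  }
  structure(list(abundance = mat,
                 sample_info = data.frame(
                   sample = samples, unit = rep(units, 2),
                   fraction = rep(c("core", "invasive"), each = n_pairs),
                   stringsAsFactors = FALSE),
                 feature_kind = "metabolite", truth = NULL,
                 config = NULL), class = "paired_abundance")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("paired differential recovers exact fold changes and t p-values", {
  flat <- make_pa(matrix(5, 4, 6))
  d <- paired_differential(flat, pseudo = 0)
  expect_equal(d$fold_change, rep(1, 4))
  expect_equal(d$log2_fc, rep(0, 4))
  expect_equal(d$p_value, rep(1, 4))

  base <- matrix(rep(c(3, 8, 2), 3), 3, 3)
  doubled <- make_pa(cbind(base, 2 * base))
  d2 <- paired_differential(doubled, pseudo = 0)
  expect_equal(d2$fold_change, rep(2, 3))

  # 7-pair feature against the closed-form paired t on the log ratios
  set.seed(31)
  core <- matrix(2^rnorm(7, 10), 1, 7)
  inv <- matrix(2^rnorm(7, 11), 1, 7)
  pa <- make_pa(cbind(core, inv))
  d3 <- paired_differential(pa, pseudo = 0)
  expect_equal(d3$p_value,
               bf_one_sample_t_p(log2(as.numeric(inv)) -
                                 log2(as.numeric(core))))

  expect_error(paired_differential(make_pa(matrix(1, 2, 2))), "pairs")
})

test_that("top-k ranking uses fold change with p then lexical tie-breaks", {
  d <- data.frame(feature = c("cysta", "amino", "nicot"),
                  fold_change = c(9.6, 5.0, 1.9),
                  log2_fc = log2(c(9.6, 5.0, 1.9)),
                  p_value = c(0.01, 0.003, 0.002),
                  p_adjusted = c(0.03, 0.009, 0.006),
                  direction = "up_invasive")
  expect_equal(rank_top(d, k = 1)$feature, "cysta")

  ties <- data.frame(feature = c("b", "a", "c"), fold_change = 2,
                     log2_fc = 1, p_value = c(0.5, 0.5, 0.01),
                     p_adjusted = 0.5, direction = "up_invasive")
  expect_equal(rank_top(ties, k = 3)$feature, c("c", "a", "b"))
  expect_error(rank_top(d, k = 0), "out of range")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(32)
  p <- runif(50)
  expect_equal(bh_adjust(p), bf_bh(p))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("median-of-ratios factors match hand computation and are idempotent", {
  a <- c(10, 20, 30, 40, 50)
  m <- cbind(s1 = a, s2 = a)
  gn <- geomean_normalize(m)
  expect_equal(gn$size_factors, c(s1 = 1, s2 = 1))

  m2 <- cbind(s1 = a, s2 = 2 * a)
  gn2 <- geomean_normalize(m2)
  expect_equal(unname(gn2$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(gn2$normalized[, 1], gn2$normalized[, 2],
               ignore_attr = TRUE)

  # 5-feature toy matrix vs hand-computed medians of ratios
  m3 <- cbind(s1 = c(4, 10, 20, 8, 100), s2 = c(16, 10, 5, 32, 100))
  ref <- exp(rowMeans(log(m3)))
  hand <- apply(m3 / ref, 2, median)
  expect_equal(geomean_normalize(m3)$size_factors, hand)

  again <- geomean_normalize(geomean_normalize(m3)$normalized)
  expect_equal(unname(again$size_factors), c(1, 1), tolerance = 1e-8)

  withzero <- cbind(c(0, 5), c(1, 0))
  expect_error(geomean_normalize(withzero), "zero-free")
})

test_that("over-representation equals exact hypergeometric enumeration", {
  # universe 20, set 5, hits 5, overlap 4
  universe <- sprintf("g%02d", 1:20)
  sets <- list(path = universe[1:5])
  hits <- universe[c(1:4, 20)]
  res <- ora_enrichment(hits, sets, universe)
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, bf_hyper_p(4, 5, 20, 5))

  # complete overlap of hits with the only set
  res2 <- ora_enrichment(universe[1:5], list(s = universe[1:5]),
                         universe[1:5])
  expect_equal(res2$overlap, 5)
  expect_equal(res2$p_value, 1)

  # members outside the universe are dropped with a message
  expect_message(
    res3 <- ora_enrichment(universe[1:2],
                           list(s = c(universe[1:3], "alien")),
                           universe),
    "outside universe")
  expect_equal(res3$n_set, 3)

  set.seed(33)
  many <- lapply(1:8, function(i) sample(universe, sample(3:10, 1)))
  names(many) <- paste0("set", 1:8)
  res4 <- ora_enrichment(sample(universe, 6), many, universe)
  expect_true(all(res4$q_value >= res4$p_value))
  expect_error(ora_enrichment("x", list(a = "x"), character(0)),
               "empty universe")
})

test_that("concordance reports Pearson r and strict sign discordance", {
  fc <- c(a = 1, b = -2, c = 0.5, d = 3)
  res <- concordance(fc, fc)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$pct_discordant, 0)

  res2 <- concordance(fc, -fc)
  expect_equal(res2$pearson_r, -1)
  expect_equal(res2$pct_discordant, 100)

  # printed worked example: 20 discordant of 322 genes
  set.seed(34)
  a <- abs(rnorm(322)) + 0.01
  b <- a
  b[1:20] <- -b[1:20]
  names(a) <- names(b) <- sprintf("g%03d", 1:322)
  res3 <- concordance(a, b)
  expect_equal(res3$n_discordant, 20)
  expect_equal(res3$pct_discordant, 6.2)

  # invariant to feature order and positive rescaling
  perm <- sample(names(a))
  expect_equal(concordance(a[perm], b)$pct_discordant, 6.2)
  expect_equal(concordance(3.7 * a, 0.2 * b)$pct_discordant, 6.2)

  expect_error(concordance(c(x = 1, y = 2), c(x = 1, y = 2)), "3 shared")
})

test_that("metabolic subsetting reports the printed 16% worked example", {
  degs <- sprintf("deg%04d", 1:2172)
  catalog <- c(degs[1:344], sprintf("other%d", 1:500))
  res <- subset_metabolic(degs, catalog)
  expect_equal(res$n_metabolic, 344)
  expect_equal(res$pct, 16L)

  expect_equal(subset_metabolic(degs[1:10], degs)$pct, 100L)
  expect_equal(subset_metabolic(degs[1:10], "nope")$pct, 0L)
  expect_error(subset_metabolic(character(0), degs), "empty")
})

test_that("abundance PCA separates fractions when effects are large", {
  sim <- simulate_paired_abundance(abundance_sim_config(
    n_features = 200L, n_pairs = 5L, frac_changed = 0.3,
    effect_log2 = 4, noise_sd_log = 0.3, seed = 35L))
  pca <- pca_scores(sim)
  expect_lte(sum(pca$var_explained), 1 + 1e-8)
  expect_gt(bf_silhouette(pca$scores[, 1], pca$sample_info$fraction), 0)

  same <- make_pa(matrix(7, 5, 4))
  expect_equal(sum(pca_scores(same)$var_explained), 0)
  expect_error(pca_scores(make_pa(matrix(1, 3, 2))), "3 samples")
})
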