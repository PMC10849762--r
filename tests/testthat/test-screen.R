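# hand-built two-guide screen for the normalization arithmetic
tiny_screen <- function(counts, fraction) {
  structure(list(
    counts = counts,
    guide_info = data.frame(guide_id = rownames(counts),
                            gene = rep("g1", nrow(counts)),
                            is_nontargeting = FALSE,
                            stringsAsFactors = FALSE),
    sample_info = data.frame(sample = colnames(counts),
                             fraction = fraction,
                             replicate = seq_along(fraction),
                             stringsAsFactors = FALSE),
    truth = NULL, config = NULL), class = "screen_counts")
}

test_that("pooling sums replicates and scales each fraction to CPM", {
  counts <- matrix(c(10, 90, 40, 360), 2,
                   dimnames = list(c("a", "b"), c("core_1", "invasive_1")))
  norm <- pool_and_normalize(tiny_screen(counts, c("core", "invasive")))
  expect_equal(norm$cpm_core, c(1e5, 9e5))
  expect_equal(norm$cpm_invasive, c(1e5, 9e5))

  counts2 <- matrix(c(1, 9, 9, 81, 5, 5), 2,
                    dimnames = list(c("a", "b"),
                                    c("core_1", "core_2", "invasive_1")))
  norm2 <- pool_and_normalize(tiny_screen(counts2,
                                          c("core", "core", "invasive")))
  expect_equal(norm2$cpm_core, c(1e5, 9e5))  # pooled [10, 90]

  # scale invariance: multiplying one sample by 7 leaves CPM unchanged
  counts3 <- counts2
  counts3[, "core_2"] <- counts3[, "core_2"] * 7
  norm3 <- pool_and_normalize(tiny_screen(counts3,
                                          c("core", "core", "invasive")))
  expect_equal(norm3$cpm_invasive, norm2$cpm_invasive)

  zero <- matrix(c(0, 0, 5, 5), 2,
                 dimnames = list(c("a", "b"), c("core_1", "invasive_1")))
  expect_error(pool_and_normalize(tiny_screen(zero,
                                              c("core", "invasive"))),
               "zero total")
})

test_that("guide fitness is the centered log2 invasive/core ratio", {
  norm <- data.frame(guide_id = c("t1", "nt1", "nt2", "nt3"),
                     gene = c("g1", NA, NA, NA),
                     is_nontargeting = c(FALSE, TRUE, TRUE, TRUE),
                     cpm_core = c(100, 100, 100, 100),
                     cpm_invasive = c(25, 100, 100, 100))
  fit <- guide_fitness(norm, pseudocount = 0)
  expect_equal(fit$fitness[1], -2)  # log2(25/100), nontargeting median 0
  expect_equal(fit$fitness[2:4], rep(0, 3))

  # nontargeting median +0.5 shifts a raw -0.7 guide to -1.2
  norm2 <- data.frame(guide_id = c("t1", "nt1", "nt2", "nt3"),
                      gene = c("g1", NA, NA, NA),
                      is_nontargeting = c(FALSE, TRUE, TRUE, TRUE),
                      cpm_core = c(100, 100, 100, 100),
                      cpm_invasive = c(100 * 2^-0.7, 100 * 2^0.4,
                                       100 * 2^0.5, 100 * 2^0.6))
  fit2 <- guide_fitness(norm2, pseudocount = 0)
  nt_median <- median(log2(norm2$cpm_invasive[2:4] / 100))
  expect_equal(nt_median, 0.5)
  expect_equal(fit2$fitness[1], -1.2)
  expect_equal(median(fit2$fitness[fit2$is_nontargeting]), 0)

  norm3 <- norm[1, , drop = FALSE]
  expect_warning(guide_fitness(norm3, pseudocount = 0.5),
                 "no nontargeting")
})

test_that("gene scores are guide medians with one-sample t p-values", {
  fit <- data.frame(guide_id = paste0("sg", 1:3), gene = "g1",
                    is_nontargeting = FALSE,
                    fitness_raw = c(-2, -1, 0.5),
                    fitness = c(-2, -1, 0.5))
  gs <- gene_score(fit)
  expect_equal(gs$score, -1)

  zero <- transform(fit, fitness = 0, fitness_raw = 0)
  gz <- gene_score(zero)
  expect_equal(gz$score, 0)
  expect_equal(gz$p_value, 1)

  v <- c(-1.0, -1.2, -0.8, -1.1, -0.9)
  five <- data.frame(guide_id = paste0("sg", 1:5), gene = "g1",
                     is_nontargeting = FALSE, fitness_raw = v,
                     fitness = v)
  expect_equal(gene_score(five)$p_value, bf_one_sample_t_p(v))

  single <- fit[1, ]
  gs1 <- gene_score(single)
  expect_equal(gs1$score, -2)
  expect_true(is.na(gs1$p_value))
})

test_that("hit calling applies score and p cutoffs with direction", {
  scores <- data.frame(gene = c("cth_like", "sms_like", "up", "null"),
                       score = c(-1.2, -1.8, 1.5, 0),
                       p_value = c(0.01, 0.09, 0.001, 0.9),
                       n_guides = 10L)
  hits <- call_hits(scores, score_threshold = 1, p_threshold = 0.05)
  expect_setequal(hits$gene, c("cth_like", "up"))
  expect_equal(hits$direction[hits$gene == "cth_like"], "core_enriched")
  expect_equal(hits$direction[hits$gene == "up"], "invasive_enriched")
  expect_false("sms_like" %in% hits$gene)  # fails the p cut

  all_zero <- data.frame(gene = letters[1:3], score = 0,
                         p_value = c(0.5, 0.01, 1), n_guides = 5L)
  expect_equal(nrow(call_hits(all_zero, 1, 0.05)), 0)
  expect_error(call_hits(scores, score_threshold = 0), "out of range")
  expect_error(call_hits(scores, p_threshold = -1), "out of range")
})

test_that("nontargeting centering and scale invariance hold on simulations", {
  sim <- simulate_screen_counts(screen_sim_config(
    n_genes = 80L, guides_per_gene = 5L, n_nontargeting = 41L,
    mean_depth = 300, n_core_samples = 1L, n_invasive_samples = 1L,
    seed = 12L))
  fit <- score_screen(sim)
  expect_equal(median(fit$guides$fitness[fit$guides$is_nontargeting]), 0)

  # sequencing one fraction 5x deeper leaves fitness unchanged
  scaled <- sim
  scaled$counts[, 1] <- scaled$counts[, 1] * 5L
  fit2 <- score_screen(scaled)
  expect_equal(fit2$guides$fitness, fit$guides$fitness)

  # with replicates, a global depth change of a fraction cancels too
  sim2 <- simulate_screen_counts(screen_sim_config(
    n_genes = 80L, guides_per_gene = 5L, n_nontargeting = 41L,
    mean_depth = 300, n_core_samples = 2L, n_invasive_samples = 2L,
    seed = 12L))
  fitr <- score_screen(sim2)
  scaled2 <- sim2
  core_cols <- sim2$sample_info$fraction == "core"
  scaled2$counts[, core_cols] <- scaled2$counts[, core_cols] * 3L
  expect_equal(score_screen(scaled2)$guides$fitness, fitr$guides$fitness)
})

test_that("gene medians resist a single corrupted guide", {
  sim <- simulate_screen_counts(screen_sim_config(
    n_genes = 40L, guides_per_gene = 5L, n_nontargeting = 21L,
    mean_depth = 300, n_core_samples = 1L, n_invasive_samples = 1L,
    seed = 13L))
  fit <- guide_fitness(pool_and_normalize(sim))
  base <- gene_score(fit)

  # corrupt the first guide of every gene with a huge outlier
  corrupt <- fit
  first <- !duplicated(corrupt$gene) & !corrupt$is_nontargeting
  corrupt$fitness[first] <- corrupt$fitness[first] + 50
  after <- gene_score(corrupt)
  shift_outlier <- abs(after$score - base$score)

  # replacing the median-defining guide everywhere shifts scores more
  expect_lt(max(shift_outlier), 50 / 2)
  expect_lt(mean(shift_outlier), 1)
})

test_that("screen PCA separates fractions under a planted effect", {
  sim <- simulate_screen_counts(screen_sim_config(
    n_genes = 150L, guides_per_gene = 5L, n_nontargeting = 50L,
    frac_essential = 0.2, effect_log2 = -3, mean_depth = 500,
    n_core_samples = 3L, n_invasive_samples = 3L, seed = 14L))
  pca <- screen_pca(sim)
  expect_true(all(pca$var_explained >= 0))
  expect_lte(sum(pca$var_explained), 1 + 1e-8)
  sil <- bf_silhouette(pca$scores[, 1], pca$sample_info$fraction)
  expect_gt(sil, 0)

  # duplicated samples land on identical coordinates
  dup <- sim
  dup$counts <- cbind(sim$counts, sim$counts)
  colnames(dup$counts) <- c(colnames(sim$counts),
                            paste0(colnames(sim$counts), "_dup"))
  dup$sample_info <- rbind(sim$sample_info, sim$sample_info)
  dup$sample_info$sample <- colnames(dup$counts)
  pd <- screen_pca(dup)
  n <- nrow(sim$sample_info)
  expect_equal(pd$scores[1:n, ], pd$scores[(n + 1):(2 * n), ],
               ignore_attr = TRUE)

  # identical samples carry zero variance
  same <- sim
  same$counts <- sim$counts[, c(1, 1)]
  colnames(same$counts) <- c("core_1", "invasive_1")
  same$sample_info <- sim$sample_info[c(1, 4), ]
  same$sample_info$sample <- colnames(same$counts)
  expect_equal(sum(screen_pca(same)$var_explained), 0)

  one <- same
  one$counts <- one$counts[, 1, drop = FALSE]
  one$sample_info <- one$sample_info[1, ]
  expect_error(screen_pca(one), "2 samples")
})
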