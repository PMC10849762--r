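#' Configuration for a simulated pooled CRISPR knockout screen
#'
#' Describes a metabolism-focused pooled knockout screen read out by
#' sequencing sgRNA abundances in the noninvasive core and the invasive
#' fraction of 3D hydrogel invasion devices. The defaults mirror a
#' metabolic library of 2,981 genes at 10 guides per gene with
#' nontargeting controls, read out in 6 devices (one core and one
#' invasive fraction each).
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides designed against each gene.
#' @param n_nontargeting Number of nontargeting control guides.
#' @param frac_essential Fraction of genes planted as invasion-essential.
#' @param effect_log2 Planted log2 change of essential-gene guide abundance
#'   in the invasive fraction; negative values mean knockout cells fail to
#'   invade and their guides are depleted at the front.
#' @param dispersion Negative-binomial overdispersion; counts have
#'   variance `mu + mu^2 * dispersion`.
#' @param mean_depth Expected reads per guide per sample.
#' @param n_core_samples,n_invasive_samples Sequenced samples per fraction.
#' @param seed Integer seed; identical configs give identical screens.
#' @return A list of class `screen_sim_config`.
#' @seealso [simulate_screen_counts()]
#' @export
screen_sim_config <- function(n_genes = 2981L, guides_per_gene = 10L,
                              n_nontargeting = 1000L,
                              frac_essential = 0.05, effect_log2 = -2,
                              dispersion = 0.2, mean_depth = 500,
                              n_core_samples = 6L, n_invasive_samples = 6L,
                              seed = 1L) {
  cfg <- list(
    n_genes = stop_if_not_count(n_genes, "n_genes"),
    guides_per_gene = stop_if_not_count(guides_per_gene, "guides_per_gene"),
    n_nontargeting = stop_if_not_count(n_nontargeting, "n_nontargeting",
                                       min = 0L),
    frac_essential = stop_if_not_scalar_number(frac_essential,
                                               "frac_essential", 0, 1),
    effect_log2 = stop_if_not_scalar_number(effect_log2, "effect_log2"),
    dispersion = stop_if_not_scalar_number(dispersion, "dispersion",
                                           min = 0, strict_min = TRUE),
    mean_depth = stop_if_not_scalar_number(mean_depth, "mean_depth",
                                           min = 0, strict_min = TRUE),
    n_core_samples = stop_if_not_count(n_core_samples, "n_core_samples"),
    n_invasive_samples = stop_if_not_count(n_invasive_samples,
                                           "n_invasive_samples"),
    seed = stop_if_not_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "screen_sim_config")
}

#' Simulate guide-level counts for a pooled invasion screen
#'
#' Draws sgRNA counts for core and invasive fractions. Guide library
#' abundances are log-normal (sdlog 0.5) to mimic library skew; counts are
#' negative-binomial around the guide's expected depth. Guides against a
#' planted invasion-essential gene have their invasive-fraction mean scaled
#' by `2^effect_log2`; nontargeting guides are never perturbed.
#'
#' @param cfg A [screen_sim_config()].
#' @return A list of class `screen_counts` with elements
#'   \describe{
#'     \item{counts}{integer matrix, guides x samples.}
#'     \item{guide_info}{data frame with `guide_id`, `gene`,
#'       `is_nontargeting`.}
#'     \item{sample_info}{data frame with `sample`, `fraction`
#'       (`"core"`/`"invasive"`), `replicate`.}
#'     \item{truth}{data frame of genes with logical `essential` flags.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' sim <- simulate_screen_counts(screen_sim_config(n_genes = 50,
#'   guides_per_gene = 4, n_nontargeting = 20, mean_depth = 200, seed = 1))
#' dim(sim$counts)
#' @export
simulate_screen_counts <- function(cfg = screen_sim_config()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  n_ess <- floor(cfg$frac_essential * cfg$n_genes)
  if (n_ess < 1 && cfg$effect_log2 != 0 && cfg$frac_essential > 0) {
    warning("frac_essential * n_genes < 1: no essential genes planted, ",
            "effect_log2 has no effect")
  }
  with_seed(cfg$seed, {
    genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    gene_of_guide <- rep(genes, each = cfg$guides_per_gene)
    n_target <- cfg$n_genes * cfg$guides_per_gene
    guide_id <- c(
      sprintf("%s_sg%d", gene_of_guide, rep(seq_len(cfg$guides_per_gene),
                                            times = cfg$n_genes)),
      sprintf("nontargeting_sg%04d", seq_len(cfg$n_nontargeting))
    )
    guide_info <- data.frame(
      guide_id = guide_id,
      gene = c(gene_of_guide, rep(NA_character_, cfg$n_nontargeting)),
      is_nontargeting = c(rep(FALSE, n_target),
                          rep(TRUE, cfg$n_nontargeting)),
      stringsAsFactors = FALSE
    )
    n_guides <- nrow(guide_info)

    essential <- rep(FALSE, cfg$n_genes)
    if (n_ess >= 1) essential[sample.int(cfg$n_genes, n_ess)] <- TRUE
    truth <- data.frame(gene = genes, essential = essential,
                        stringsAsFactors = FALSE)

    # library skew: log-normal baseline, rescaled to the requested depth
    base <- stats::rlnorm(n_guides, meanlog = 0, sdlog = 0.5)
    mu_core <- cfg$mean_depth * base / mean(base)
    ess_guide <- !guide_info$is_nontargeting &
      guide_info$gene %in% genes[essential]
    mu_inv <- mu_core
    mu_inv[ess_guide] <- mu_inv[ess_guide] * 2^cfg$effect_log2

    samples <- c(sprintf("core_%d", seq_len(cfg$n_core_samples)),
                 sprintf("invasive_%d", seq_len(cfg$n_invasive_samples)))
    fraction <- rep(c("core", "invasive"),
                    c(cfg$n_core_samples, cfg$n_invasive_samples))
    size <- 1 / cfg$dispersion
    counts <- matrix(0L, n_guides, length(samples),
                     dimnames = list(guide_info$guide_id, samples))
    for (j in seq_along(samples)) {
      mu <- if (fraction[j] == "core") mu_core else mu_inv
      counts[, j] <- stats::rnbinom(n_guides, mu = mu, size = size)
    }

    structure(list(
      counts = counts,
      guide_info = guide_info,
      sample_info = data.frame(
        sample = samples, fraction = fraction,
        replicate = c(seq_len(cfg$n_core_samples),
                      seq_len(cfg$n_invasive_samples)),
        stringsAsFactors = FALSE
      ),
      truth = truth,
      config = cfg
    ), class = "screen_counts")
  })
}

#' Configuration for simulated paired core/invasive abundance matrices
#'
#' Emulates the paired experimental design in which each unit (a hydrogel
#' invasion device or a patient tumor) contributes one core and one
#' invasive-front sample of metabolite, lipid, or gene abundances.
#' Defaults reflect a hydrogel metabolomics cohort of 7 paired devices.
#'
#' @param n_features Number of measured features.
#' @param n_pairs Number of paired units (>= 2).
#' @param frac_changed Fraction of features with a true invasive/core
#'   change.
#' @param effect_log2 log2 shift applied to changed features in the
#'   invasive member of every pair.
#' @param noise_sd_log Standard deviation of log2 measurement noise.
#' @param feature_kind One of `"metabolite"`, `"lipid"`, `"gene"`.
#' @param seed Integer seed.
#' @return A list of class `abundance_sim_config`.
#' @export
abundance_sim_config <- function(n_features = 500L, n_pairs = 7L,
                                 frac_changed = 0.05, effect_log2 = 3,
                                 noise_sd_log = 0.5,
                                 feature_kind = c("metabolite", "lipid",
                                                  "gene"),
                                 seed = 1L) {
  cfg <- list(
    n_features = stop_if_not_count(n_features, "n_features"),
    n_pairs = stop_if_not_count(n_pairs, "n_pairs", min = 2L),
    frac_changed = stop_if_not_scalar_number(frac_changed, "frac_changed",
                                             0, 1),
    effect_log2 = stop_if_not_scalar_number(effect_log2, "effect_log2"),
    noise_sd_log = stop_if_not_scalar_number(noise_sd_log, "noise_sd_log",
                                             min = 0),
    feature_kind = match.arg(feature_kind),
    seed = stop_if_not_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "abundance_sim_config")
}

#' Simulate a paired core/invasive abundance matrix
#'
#' Feature baselines are log-normal; every sample adds log2-normal
#' measurement noise, and the invasive member of each pair of a truly
#' changed feature is shifted by `effect_log2` on the log2 scale.
#'
#' @param cfg An [abundance_sim_config()].
#' @return A list of class `paired_abundance` with elements `abundance`
#'   (positive matrix, features x samples), `sample_info` (`sample`,
#'   `unit`, `fraction`), `feature_kind`, `truth` (data frame with
#'   `feature`, `changed`), and `config`.
#' @examples
#' sim <- simulate_paired_abundance(abundance_sim_config(n_features = 50,
#'   n_pairs = 4, seed = 2))
#' head(sim$truth)
#' @export
simulate_paired_abundance <- function(cfg = abundance_sim_config()) {
  stopifnot(inherits(cfg, "abundance_sim_config"))
  with_seed(cfg$seed, {
    features <- sprintf("feat_%04d", seq_len(cfg$n_features))
    n_changed <- floor(cfg$frac_changed * cfg$n_features)
    changed <- rep(FALSE, cfg$n_features)
    if (n_changed >= 1) changed[sample.int(cfg$n_features, n_changed)] <- TRUE

    base_log2 <- stats::rnorm(cfg$n_features, mean = 10, sd = 2)
    units <- sprintf("unit_%02d", seq_len(cfg$n_pairs))
    samples <- c(paste0(units, "_core"), paste0(units, "_invasive"))
    fraction <- rep(c("core", "invasive"), each = cfg$n_pairs)

    log2_mat <- matrix(base_log2, cfg$n_features, 2L * cfg$n_pairs)
    log2_mat[changed, fraction == "invasive"] <-
      log2_mat[changed, fraction == "invasive"] + cfg$effect_log2
    log2_mat <- log2_mat + stats::rnorm(length(log2_mat),
                                        sd = cfg$noise_sd_log)
    abundance <- 2^log2_mat
    dimnames(abundance) <- list(features, samples)

    structure(list(
      abundance = abundance,
      sample_info = data.frame(sample = samples,
                               unit = rep(units, 2L),
                               fraction = fraction,
                               stringsAsFactors = FALSE),
      feature_kind = cfg$feature_kind,
      truth = data.frame(feature = features, changed = changed,
                         stringsAsFactors = FALSE),
      config = cfg
    ), class = "paired_abundance")
  })
}
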