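#' Boundary of a binary mask
#'
#' Foreground pixels with at least one 4-neighbor background pixel (the
#' image border counts as background). The tumor outline fed to boundary
#' -mode fractal analysis.
#'
#' @param mask A [cell_mask()].
#' @return A [cell_mask()] containing only the boundary pixels.
#' @export
boundary_mask <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  bin <- as_binary(mask)
  n <- nrow(bin); m <- ncol(bin)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- bin
  border <- bin & !(pad[1:n, 2:(m + 1L)] & pad[3:(n + 2L), 2:(m + 1L)] &
                    pad[2:(n + 1L), 1:m] & pad[2:(n + 1L), 3:(m + 2L)])
  cell_mask(matrix(as.integer(border), n, m),
            pixel_size_um = mask$pixel_size_um,
            channel_edge_um = mask$channel_edge_um,
            timepoint = mask$timepoint)
}

#' Count occupied boxes at a set of scales
#'
#' For each box size `s`, the number of `s` x `s` grid cells containing at
#' least one foreground pixel. With `n_offsets > 1` the grid is placed at
#' that many diagonal offsets and the counts are aggregated — by default
#' the minimum, which estimates the optimal covering and removes the
#' upward bias a fixed grid placement can introduce. The default single
#' offset is the grid aligned to the image origin, for which counts on
#' analytic fixtures are exact.
#'
#' @param mask A [cell_mask()] or binary matrix; must be non-empty.
#' @param box_sizes At least 2 distinct positive integer scales (pixels).
#' @param n_offsets Number of grid offsets tried (default 1).
#' @param aggregate How to combine counts across offsets: `"min"`
#'   (default) or `"mean"`.
#' @return Numeric vector of box counts, one per scale.
#' @examples
#' m <- simulate_mask("filled_square", image_size = 64, side_px = 64)
#' box_count(m, c(2, 4, 8))  # 1024 256 64
#' @export
box_count <- function(mask, box_sizes, n_offsets = 1L,
                      aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  bin <- as_binary(mask)
  if (!any(bin)) stop("empty mask: box counting undefined")
  box_sizes <- as.integer(box_sizes)
  if (length(unique(box_sizes)) < 2 || any(box_sizes < 1)) {
    stop("`box_sizes` needs >= 2 distinct positive scales")
  }
  n_offsets <- stop_if_not_count(n_offsets, "n_offsets")
  idx <- which(bin)
  r0 <- (idx - 1L) %% nrow(bin)
  c0 <- (idx - 1L) %/% nrow(bin)
  vapply(box_sizes, function(s) {
    offs <- unique(floor(seq(0, s - 1, length.out = n_offsets)))
    # symmetrize and cross the axes so the offset-grid set is closed
    # under 90-degree rotations and reflections of the mask
    offs <- unique(c(offs, (s - offs) %% s))
    grid <- expand.grid(or = offs, oc = offs)
    counts <- mapply(function(or, oc) {
      length(unique((r0 + or) %/% s + ((c0 + oc) %/% s) * 2^26))
    }, grid$or, grid$oc)
    if (aggregate == "min") min(counts) else mean(counts)
  }, numeric(1))
}

#' Box-counting fractal dimension of a tumor mask
#'
#' Estimates the fractal dimension, a numeric description of invasive
#' tumor growth pattern, as the slope of the least-squares fit of
#' `log N(s)` against `log(1/s)` over a range of box sizes. In the
#' default `boundary` mode the tumor outline is analyzed, so a planar
#' tumor section scores between 1 (smooth outline) and 2 (boundary so
#' convoluted it fills the plane), with higher values indicating greater
#' invasiveness; `filled` mode analyzes the full mask and is used for
#' validation on analytic fixtures.
#'
#' @param mask A [cell_mask()] (binary).
#' @param box_sizes Box scales in pixels; default powers of 2 from 2 to a
#'   quarter of the smaller image side. At least 3 scales are required.
#' @param mode `"boundary"` (default) or `"filled"`.
#' @param n_offsets Grid offsets tried per scale (default 4); the
#'   minimum count across offsets is used (see [box_count()]).
#' @return An object of class `fractal_fit`: list with `dimension`,
#'   `box_sizes`, `box_counts`, `fit_r2`, `mode`, and the underlying `fit`.
#' @examples
#' m <- simulate_mask("line", image_size = 128)
#' fractal_dimension(m, mode = "filled")$dimension  # ~1
#' @export
fractal_dimension <- function(mask, box_sizes = NULL,
                              mode = c("boundary", "filled"),
                              n_offsets = 4L) {
  stopifnot(inherits(mask, "cell_mask"))
  mode <- match.arg(mode)
  if (is.null(box_sizes)) {
    smax <- max(4L, min(dim(mask$pixels)) %/% 4L)
    box_sizes <- 2L^(1:floor(log2(smax)))
  }
  if (length(unique(box_sizes)) < 3) stop("need >= 3 distinct box sizes")
  target <- if (mode == "boundary") boundary_mask(mask) else mask
  counts <- box_count(target, box_sizes, n_offsets = n_offsets,
                      aggregate = "min")
  if (any(counts <= 0)) stop("zero box count; mask too sparse")
  lx <- log(1 / box_sizes)
  if (stats::sd(lx) == 0) stop("degenerate scales: zero variance")
  fit <- stats::lm(log(counts) ~ lx)
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(list(dimension = unname(stats::coef(fit)[2]),
                 box_sizes = as.integer(box_sizes),
                 box_counts = counts,
                 fit_r2 = r2, mode = mode, fit = fit),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("Box-counting fractal dimension (%s mode): D = %.4f (R^2 = %.4f)\n",
              x$mode, x$dimension, x$fit_r2))
  cat(sprintf("  %d scales: %s px\n", length(x$box_sizes),
              paste(x$box_sizes, collapse = ", ")))
  invisible(x)
}

#' Log-log box-count plot with the fitted slope
#'
#' @param x A `fractal_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fractal_fit <- function(x, ...) {
  graphics::plot(log(1 / x$box_sizes), log(x$box_counts),
                 xlab = "log(1 / box size)", ylab = "log N(boxes)",
                 pch = 16, ...)
  graphics::abline(x$fit, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("D = %.3f, R2 = %.3f",
                                    x$dimension, x$fit_r2))
  invisible(x)
}

#' Compare invasiveness between two groups of fractal dimensions
#'
#' Summarizes per-animal fractal dimensions of two groups (e.g. CTH
#' knockdown vs control xenografts) and tests for a location difference
#' with a two-sided Welch t test.
#'
#' @param group_a,group_b Numeric vectors of fractal dimensions, each of
#'   length >= 2.
#' @return List with `median_a`, `median_b`, `difference`
#'   (median_b - median_a), and `p_value`.
#' @export
compare_invasiveness <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  p <- if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) 1 else 0
  } else {
    stats::t.test(group_a, group_b)$p.value
  }
  list(median_a = stats::median(group_a),
       median_b = stats::median(group_b),
       difference = stats::median(group_b) - stats::median(group_a),
       p_value = p)
}
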