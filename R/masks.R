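#' Calibrated cell mask
#'
#' A binary or integer-labeled pixel grid with physical calibration, the
#' common container for spheroid, device, and tumor-section masks. Pixel
#' centers are at physical coordinates `x = (col - 0.5) * pixel_size_um`,
#' `y = (row - 0.5) * pixel_size_um`.
#'
#' @param pixels Integer (or logical) matrix; 0/FALSE is background.
#' @param pixel_size_um Physical pixel edge length in micrometers.
#' @param channel_edge_um Optional x-coordinate (um) of the channel edge in
#'   device assays; invasion distance is measured perpendicular to it.
#' @param timepoint Optional acquisition time in days.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(pixels, pixel_size_um = 1, channel_edge_um = NULL,
                      timepoint = NULL) {
  if (is.logical(pixels)) pixels <- matrix(as.integer(pixels),
                                           nrow(pixels), ncol(pixels))
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric or logical matrix")
  }
  if (any(pixels < 0) || any(pixels != round(pixels))) {
    stop("mask labels must be non-negative integers")
  }
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", min = 0,
                            strict_min = TRUE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_edge_um = channel_edge_um, timepoint = timepoint),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d x %d px (%.3g um/px), %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              sum(x$pixels > 0)))
  if (!is.null(x$channel_edge_um)) {
    cat(sprintf("  channel edge at x = %g um\n", x$channel_edge_um))
  }
  invisible(x)
}

as_binary <- function(mask) {
  px <- if (inherits(mask, "cell_mask")) mask$pixels else mask
  px > 0
}

#' Simulate a calibrated mask
#'
#' Generates fixture masks for the invasion and fractal pipelines:
#' analytic shapes with closed-form geometry (`disk`, `line`,
#' `filled_square`, `sierpinski_carpet`), a stochastic `branched_growth`
#' tumor whose boundary complexity rises with `branching_intensity`, a
#' `spheroid_field` (connected central spheroid plus isolated single
#' cells), and a `device_field` (cell reservoir at a channel edge plus
#' invading cells at known distances).
#'
#' @param kind Shape kind (see Details).
#' @param image_size Image side length in pixels.
#' @param pixel_size_um Pixel edge length, micrometers.
#' @param seed Seed for the stochastic kinds.
#' @param radius_px Disk radius (`disk`), pixels.
#' @param side_px Square side (`filled_square`), pixels.
#' @param depth Recursion depth (`sierpinski_carpet`); the carpet spans
#'   `3^depth` pixels and `image_size` must be at least that.
#' @param branching_intensity Non-negative real controlling the number of
#'   branches in `branched_growth`.
#' @param core_radius_px Radius of the central spheroid / reservoir blob.
#' @param n_cells Number of scattered single cells (`spheroid_field`,
#'   `device_field`).
#' @param cell_centers_um Optional n x 2 matrix of (x, y) single-cell
#'   centers, um, overriding random placement.
#' @param channel_edge_um Channel-edge x-coordinate for `device_field`.
#' @param cell_distances_um Optional distances (um) of scattered cells
#'   beyond the channel edge in `device_field`.
#' @return A [cell_mask()]. Stochastic kinds attach the placed single-cell
#'   centers as attribute `"cell_centers_um"`.
#' @examples
#' m <- simulate_mask("disk", image_size = 128, radius_px = 50)
#' measure_area(m)
#' @export
simulate_mask <- function(kind = c("disk", "line", "filled_square",
                                   "sierpinski_carpet", "branched_growth",
                                   "spheroid_field", "device_field"),
                          image_size = 256L, pixel_size_um = 1, seed = 1L,
                          radius_px = image_size / 4,
                          side_px = image_size / 2,
                          depth = 4L,
                          branching_intensity = 1,
                          core_radius_px = image_size / 8,
                          n_cells = 10L,
                          cell_centers_um = NULL,
                          channel_edge_um = image_size * pixel_size_um / 8,
                          cell_distances_um = NULL) {
  kind <- match.arg(kind)
  image_size <- stop_if_not_count(image_size, "image_size")
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", min = 0,
                            strict_min = TRUE)
  px <- matrix(0L, image_size, image_size)
  centers <- NULL

  col_x <- function(i) (i - 0.5) * pixel_size_um
  fill_disk <- function(px, cx, cy, r) {
    # cx, cy, r in pixel units
    rows <- matrix(seq_len(image_size), image_size, image_size)
    cols <- t(rows)
    px[(rows - 0.5 - cy)^2 + (cols - 0.5 - cx)^2 <= r^2] <- 1L
    px
  }

  if (kind == "disk") {
    if (2 * radius_px > image_size) stop("disk does not fit in the image")
    px <- fill_disk(px, image_size / 2, image_size / 2, radius_px)
  } else if (kind == "line") {
    px[floor(image_size / 2), ] <- 1L
  } else if (kind == "filled_square") {
    if (side_px > image_size) stop("square does not fit in the image")
    off <- floor((image_size - side_px) / 2)
    px[off + seq_len(side_px), off + seq_len(side_px)] <- 1L
  } else if (kind == "sierpinski_carpet") {
    depth <- stop_if_not_count(depth, "depth", min = 0L)
    side <- 3L^depth
    if (side > image_size) stop("carpet (3^depth px) does not fit in the image")
    idx0 <- seq_len(side) - 1L
    # a cell is filled iff no base-3 digit pair is (1, 1)
    digit_ok <- matrix(TRUE, side, side)
    for (k in seq_len(depth)) {
      d <- (idx0 %/% 3L^(k - 1L)) %% 3L
      digit_ok <- digit_ok & !outer(d == 1L, d == 1L, "&")
    }
    px[seq_len(side), seq_len(side)][digit_ok] <- 1L
  } else if (kind == "branched_growth") {
    stop_if_not_scalar_number(branching_intensity, "branching_intensity",
                              min = 0)
    px <- with_seed(seed, {
      m <- fill_disk(px, image_size / 2, image_size / 2,
                     max(2, image_size / 16))
      n_branches <- max(1L, round(4 * branching_intensity))
      for (b in seq_len(n_branches)) {
        ang <- stats::runif(1, 0, 2 * pi)
        x <- image_size / 2
        y <- image_size / 2
        n_steps <- round(stats::runif(1, 0.25, 0.45) * image_size)
        for (s in seq_len(n_steps)) {
          ang <- ang + stats::rnorm(1, sd = 0.15)
          x <- x + cos(ang)
          y <- y + sin(ang)
          r <- round(y); c <- round(x)
          if (r < 1 || r > image_size || c < 1 || c > image_size) break
          m[r, c] <- 1L
        }
      }
      m
    })
  } else if (kind == "spheroid_field") {
    res <- with_seed(seed, {
      m <- fill_disk(px, image_size / 2, image_size / 2, core_radius_px)
      ctr <- place_cells(n_cells, cell_centers_um, image_size,
                         pixel_size_um,
                         forbidden_radius_px = core_radius_px + 3,
                         centre = c(image_size / 2, image_size / 2))
      list(m = stamp_cells(m, ctr, pixel_size_um), centers = ctr)
    })
    px <- res$m; centers <- res$centers
  } else if (kind == "device_field") {
    edge_px <- channel_edge_um / pixel_size_um
    if (edge_px < 0 || edge_px > image_size) {
      stop("channel edge lies outside the image")
    }
    res <- with_seed(seed, {
      m <- px
      m[, seq_len(max(1L, floor(edge_px)))] <- 1L  # cell reservoir strip
      if (is.null(cell_centers_um)) {
        if (is.null(cell_distances_um)) {
          cell_distances_um <- stats::runif(n_cells, 5,
            (image_size - edge_px - 2) * pixel_size_um)
        }
        ys <- stats::runif(length(cell_distances_um),
                           2 * pixel_size_um,
                           (image_size - 2) * pixel_size_um)
        ctr <- cbind(x = channel_edge_um + cell_distances_um, y = ys)
      } else ctr <- cell_centers_um
      list(m = stamp_cells(m, ctr, pixel_size_um), centers = ctr)
    })
    px <- res$m; centers <- res$centers
  }

  mask <- cell_mask(px, pixel_size_um = pixel_size_um,
                    channel_edge_um = if (kind == "device_field")
                      channel_edge_um else NULL)
  if (!is.null(centers)) attr(mask, "cell_centers_um") <- centers
  mask
}

# random single-cell centers (um) outside a forbidden central radius
place_cells <- function(n_cells, cell_centers_um, image_size,
                        pixel_size_um, forbidden_radius_px, centre) {
  if (!is.null(cell_centers_um)) return(cell_centers_um)
  ctr <- matrix(NA_real_, 0, 2)
  lim <- (image_size - 2) * pixel_size_um
  while (nrow(ctr) < n_cells) {
    cand <- cbind(stats::runif(n_cells, 2 * pixel_size_um, lim),
                  stats::runif(n_cells, 2 * pixel_size_um, lim))
    d_centre <- sqrt((cand[, 1] / pixel_size_um - centre[1])^2 +
                     (cand[, 2] / pixel_size_um - centre[2])^2)
    ctr <- rbind(ctr, cand[d_centre > forbidden_radius_px, , drop = FALSE])
  }
  ctr <- ctr[seq_len(n_cells), , drop = FALSE]
  colnames(ctr) <- c("x", "y")
  ctr
}

# stamp single-pixel cells at (x, y) um coordinates
stamp_cells <- function(m, centers_um, pixel_size_um) {
  if (is.null(centers_um) || nrow(centers_um) == 0) return(m)
  cols <- pmax(1L, pmin(ncol(m), ceiling(centers_um[, 1] / pixel_size_um)))
  rows <- pmax(1L, pmin(nrow(m), ceiling(centers_um[, 2] / pixel_size_um)))
  m[cbind(rows, cols)] <- 1L
  m
}
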