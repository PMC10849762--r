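#' Total foreground area of a mask
#'
#' @param mask A [cell_mask()].
#' @return Area in square micrometers (foreground pixel count times
#'   `pixel_size_um^2`). An empty mask returns 0 with a warning.
#' @export
measure_area <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  n_fg <- sum(mask$pixels > 0)
  if (n_fg == 0) warning("empty mask: area is 0")
  n_fg * mask$pixel_size_um^2
}

#' Invasion index
#'
#' The relative area gain of a spheroid or cell reservoir between two
#' time points: `(area_final - area_initial) / area_initial`. Negative if
#' the outlined area shrank.
#'
#' @param area_initial,area_final Areas in consistent units;
#'   `area_initial` must be positive.
#' @return Dimensionless invasion index.
#' @examples
#' invasion_index(100, 300)  # 2
#' @export
invasion_index <- function(area_initial, area_final) {
  if (any(area_initial <= 0)) stop("`area_initial` must be positive")
  (area_final - area_initial) / area_initial
}

#' Normalize invasion indices to a control group
#'
#' @param indices Invasion indices to normalize.
#' @param control_indices Indices of the control condition; their mean
#'   must be positive and becomes 1 after normalization.
#' @return `indices / mean(control_indices)`.
#' @export
normalize_to_control <- function(indices, control_indices) {
  m <- mean(control_indices)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  indices / m
}

# 8-connectivity connected components, BFS with a vectorized frontier
label_components <- function(bin) {
  n <- nrow(bin); m <- ncol(bin)
  lab <- matrix(0L, n, m)
  todo <- which(bin)
  cur <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% n + 1L
      c <- (frontier - 1L) %/% n + 1L
      nr <- rep(r, each = 8L) + off_r
      nc <- rep(c, each = 8L) + off_c
      ok <- nr >= 1L & nr <= n & nc >= 1L & nc <= m
      idx <- unique((nc[ok] - 1L) * n + nr[ok])
      idx <- idx[bin[idx] & lab[idx] == 0L]
      lab[idx] <- cur
      frontier <- idx
    }
  }
  lab
}

# weighted boundary-chain perimeter (pixel units); calibrated so a
# digitized disk comes out near its true circumference
perimeter_px <- function(bin) {
  n <- nrow(bin); m <- ncol(bin)
  pad <- matrix(FALSE, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- bin
  inner <- pad[2:(n + 1L), 2:(m + 1L)]
  # border pixels: foreground with a background 4-neighbor
  border <- inner & !(pad[1:n, 2:(m + 1L)] & pad[3:(n + 2L), 2:(m + 1L)] &
                      pad[2:(n + 1L), 1:m] & pad[2:(n + 1L), 3:(m + 2L)])
  bpad <- matrix(0L, n + 2L, m + 2L)
  bpad[2:(n + 1L), 2:(m + 1L)] <- border
  code <- bpad[2:(n + 1L), 2:(m + 1L)] +
    2L * (bpad[1:n, 2:(m + 1L)] + bpad[3:(n + 2L), 2:(m + 1L)] +
          bpad[2:(n + 1L), 1:m] + bpad[2:(n + 1L), 3:(m + 2L)]) +
    10L * (bpad[1:n, 1:m] + bpad[1:n, 3:(m + 2L)] +
           bpad[3:(n + 2L), 1:m] + bpad[3:(n + 2L), 3:(m + 2L)])
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  w[c(21, 33) + 1L] <- sqrt(2)
  w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  sum(w[code[border] + 1L])
}

#' Segment a mask into per-cell objects
#'
#' Extracts connected components (8-connectivity) from a binary mask, or
#' uses existing labels of a labeled mask, and measures each object:
#' centroid, area, perimeter (weighted boundary-chain estimator), aspect
#' ratio (major/minor axis of the second-moment best-fit ellipse, so it is
#' rotation invariant), and form factor `4*pi*area / perimeter^2`
#' (circularity: 1 for a circle, lower for elongated mesenchymal shapes).
#'
#' @param mask A [cell_mask()].
#' @return A data frame with one row per object: `label`, `x_um`, `y_um`
#'   (centroid), `area_um2`, `perimeter_um`, `aspect_ratio`,
#'   `form_factor`, and `distance_to_channel_um` (signed distance of the
#'   centroid beyond the channel edge; NA without a channel edge). Empty
#'   mask gives zero rows.
#' @export
segment_cells <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  lab <- if (max(px) > 1L) px else label_components(px > 0)
  labels <- sort(unique(lab[lab > 0]))
  psz <- mask$pixel_size_um
  out <- lapply(labels, function(l) {
    idx <- which(lab == l)
    r <- (idx - 1L) %% nrow(lab) + 1L
    c <- (idx - 1L) %/% nrow(lab) + 1L
    a_px <- length(idx)
    # second moments with the 1/12 pixel-extent term so 1-px-wide
    # objects have a finite minor axis
    vr <- (if (a_px > 1) stats::var(r) * (a_px - 1) / a_px else 0) + 1 / 12
    vc <- (if (a_px > 1) stats::var(c) * (a_px - 1) / a_px else 0) + 1 / 12
    vrc <- if (a_px > 1) stats::cov(r, c) * (a_px - 1) / a_px else 0
    tr <- vr + vc
    det <- vr * vc - vrc^2
    disc <- sqrt(max(0, tr^2 / 4 - det))
    l1 <- tr / 2 + disc
    l2 <- max(tr / 2 - disc, 1e-12)
    sub <- matrix(FALSE, diff(range(r)) + 3L, diff(range(c)) + 3L)
    sub[cbind(r - min(r) + 2L, c - min(c) + 2L)] <- TRUE
    per_px <- perimeter_px(sub)
    data.frame(
      label = l,
      x_um = (mean(c) - 0.5) * psz,
      y_um = (mean(r) - 0.5) * psz,
      area_um2 = a_px * psz^2,
      perimeter_um = per_px * psz,
      aspect_ratio = sqrt(l1 / l2),
      form_factor = 4 * pi * a_px / per_px^2,
      stringsAsFactors = FALSE
    )
  })
  cells <- if (length(out)) do.call(rbind, out) else
    data.frame(label = integer(), x_um = numeric(), y_um = numeric(),
               area_um2 = numeric(), perimeter_um = numeric(),
               aspect_ratio = numeric(), form_factor = numeric())
  cells$distance_to_channel_um <- if (is.null(mask$channel_edge_um))
    rep(NA_real_, nrow(cells)) else cells$x_um - mask$channel_edge_um
  cells
}

#' Detached cells by the 10-micrometer neighbor rule
#'
#' A detached cell is a single cell with no neighboring cell within
#' `radius_um`: a neighbor at a distance less than or equal to the radius
#' blocks detachment. A lone cell in the image is detached.
#'
#' @param cells Data frame from [segment_cells()].
#' @param radius_um Neighborhood radius in micrometers (default 10).
#' @param distance_mode `"centroid"` measures center-to-center distance;
#'   `"edge"` subtracts the equivalent-circle radii of both cells to
#'   approximate the boundary gap.
#' @param max_cell_area_um2 Only objects up to this area count as single
#'   cells (candidates for detachment); larger objects — a spheroid core,
#'   a cell reservoir — still block detachment of their neighbors.
#'   Default `Inf` (every object is a candidate).
#' @return The rows of `cells` that are detached.
#' @export
detect_detached <- function(cells, radius_um = 10,
                            distance_mode = c("centroid", "edge"),
                            max_cell_area_um2 = Inf) {
  stop_if_not_scalar_number(radius_um, "radius_um", min = 0,
                            strict_min = TRUE)
  distance_mode <- match.arg(distance_mode)
  n <- nrow(cells)
  if (n == 0) return(cells)
  candidate <- cells$area_um2 <= max_cell_area_um2
  if (n == 1) return(cells[candidate, , drop = FALSE])
  d <- as.matrix(stats::dist(cells[, c("x_um", "y_um")]))
  if (distance_mode == "edge") {
    r_eq <- sqrt(cells$area_um2 / pi)
    d <- d - outer(r_eq, r_eq, "+")
  }
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  cells[candidate & nn > radius_um, , drop = FALSE]
}

#' Flag highly invasive cells by distance from the channel edge
#'
#' A cell is highly invasive when its centroid lies strictly more than
#' `threshold_um` beyond the channel edge (invasion distance > 200 um by
#' default).
#'
#' @param cells Data frame from [segment_cells()].
#' @param channel_edge_um Channel-edge x-coordinate in micrometers; taken
#'   from the cells' `distance_to_channel_um` column when omitted.
#' @param threshold_um Invasion-distance cutoff, strict (default 200).
#' @return Logical vector, one flag per cell.
#' @export
classify_invasive <- function(cells, channel_edge_um = NULL,
                              threshold_um = 200) {
  stop_if_not_scalar_number(threshold_um, "threshold_um", min = 0)
  d <- if (!is.null(channel_edge_um)) {
    cells$x_um - channel_edge_um
  } else cells$distance_to_channel_um
  if (any(is.na(d))) stop("channel edge undefined for these cells")
  d > threshold_um
}

#' Classify cell morphology by aspect ratio
#'
#' Cells with an aspect ratio of 2 or more are elongated (mesenchymal);
#' below 2 they are round.
#'
#' @param cells Data frame from [segment_cells()] (or any data frame with
#'   an `aspect_ratio` column).
#' @return Character vector, `"elongated"` or `"round"`.
#' @export
classify_morphology <- function(cells) {
  ifelse(cells$aspect_ratio >= 2, "elongated", "round")
}
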