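#' Write and read guide-level screen counts as TSV
#'
#' The TSV carries `guide_id`, `gene`, `is_nontargeting`, then one integer
#' column per sample. Sample fractions are taken from a sample-info data
#' frame, or inferred from sample names containing "core"/"invasive".
#'
#' @param screen A `screen_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_guide_counts <- function(screen, path) {
  stopifnot(inherits(screen, "screen_counts"))
  df <- data.frame(screen$guide_info, screen$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_guide_counts
#' @param sample_info Optional data frame (`sample`, `fraction`,
#'   `replicate`); inferred from column names when omitted.
#' @export
read_guide_counts <- function(path, sample_info = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta_cols <- c("guide_id", "gene", "is_nontargeting")
  stopifnot(all(meta_cols %in% names(df)))
  sample_cols <- setdiff(names(df), meta_cols)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(counts) <- df$guide_id
  if (is.null(sample_info)) {
    fraction <- ifelse(grepl("invasive", sample_cols, ignore.case = TRUE),
                       "invasive",
                       ifelse(grepl("core", sample_cols,
                                    ignore.case = TRUE), "core", NA))
    if (any(is.na(fraction))) {
      stop("cannot infer fraction from sample names; pass `sample_info`")
    }
    sample_info <- data.frame(sample = sample_cols, fraction = fraction,
                              replicate = stats::ave(seq_along(fraction),
                                fraction, FUN = seq_along),
                              stringsAsFactors = FALSE)
  }
  structure(list(counts = counts,
                 guide_info = df[, meta_cols],
                 sample_info = sample_info,
                 truth = NULL, config = NULL),
            class = "screen_counts")
}

#' Write and read paired abundance matrices as TSV
#'
#' The matrix TSV is features x samples with a `feature` first column;
#' the pairing TSV has columns `sample`, `unit`, `fraction`.
#'
#' @param pa A `paired_abundance` object.
#' @param matrix_path,pairs_path Output TSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_abundance <- function(pa, matrix_path, pairs_path) {
  stopifnot(inherits(pa, "paired_abundance"))
  df <- data.frame(feature = rownames(pa$abundance), pa$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pa$sample_info, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' @rdname write_abundance
#' @param feature_kind One of `"metabolite"`, `"lipid"`, `"gene"`.
#' @export
read_abundance <- function(matrix_path, pairs_path,
                           feature_kind = c("metabolite", "lipid",
                                            "gene")) {
  feature_kind <- match.arg(feature_kind)
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "feature")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$feature
  si <- utils::read.delim(pairs_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "unit", "fraction") %in% names(si)))
  stopifnot(all(colnames(mat) %in% si$sample))
  structure(list(abundance = mat,
                 sample_info = si[match(colnames(mat), si$sample), ],
                 feature_kind = feature_kind, truth = NULL,
                 config = NULL),
            class = "paired_abundance")
}

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member identifiers.
#'
#' @param path GMT file path.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read calibrated masks
#'
#' Masks are stored as single-channel 8-bit PNG (or TIFF when the path
#' ends in .tif/.tiff and the tiff package is available) with pixel value
#' = label (255 for binary foreground), plus a JSON sidecar
#' (`<path>.json`) holding `pixel_size_um`, `channel_edge_um`, and
#' `timepoint`.
#'
#' @param mask A [cell_mask()].
#' @param path Image path (.png, .tif, .tiff).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  if (max(px) > 255) stop("labels above 255 cannot be stored as 8-bit")
  img <- (if (max(px) <= 1) px * 255L else px) / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is needed to write TIFF masks")
    }
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    png::writePNG(img, path)
  }
  jsonlite::write_json(
    list(pixel_size_um = mask$pixel_size_um,
         channel_edge_um = mask$channel_edge_um,
         timepoint = mask$timepoint),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the tiff package is needed to read TIFF masks")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- round(img * 255)
  px <- matrix(as.integer(vals), nrow(vals), ncol(vals))
  if (max(px) == 255 && all(px %in% c(0L, 255L))) px <- px %/% 255L
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  cell_mask(px,
            pixel_size_um = meta$pixel_size_um %||% 1,
            channel_edge_um = meta$channel_edge_um,
            timepoint = meta$timepoint)
}
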