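#' Two-channel STED field
#'
#' Container for a registered pair of images: a reference channel carrying
#' the boundary marker (e.g. the active-zone scaffold Bassoon) and a query
#' channel carrying the puncta whose positions are measured relative to the
#' reference boundary (e.g. a GFP-tagged endocytic protein).
#'
#' @param reference 2-D numeric matrix of nonnegative intensities.
#' @param query 2-D numeric matrix, same shape as `reference`.
#' @param pixel_size pixel size in nm/px.
#' @return an object of class `two_channel_field`.
#' @export
two_channel_field <- function(reference, query, pixel_size) {
  stop_if_not_image(reference, "reference")
  stop_if_not_image(query, "query")
  if (!identical(dim(reference), dim(query))) {
    stop("reference and query images must have identical dimensions",
         call. = FALSE)
  }
  if (any(reference < 0) || any(query < 0)) {
    stop("channel intensities must be nonnegative", call. = FALSE)
  }
  stopifnot(length(pixel_size) == 1, pixel_size > 0)
  structure(
    list(reference = reference, query = query,
         pixel_size = as.numeric(pixel_size)),
    class = "two_channel_field"
  )
}

#' @export
print.two_channel_field <- function(x, ...) {
  cat(sprintf(
    "<two_channel_field> %d x %d px @ %g nm/px (%.2f x %.2f um)\n",
    nrow(x$reference), ncol(x$reference), x$pixel_size,
    nrow(x$reference) * x$pixel_size / 1000,
    ncol(x$reference) * x$pixel_size / 1000
  ))
  invisible(x)
}

#' Rectangular region of interest
#'
#' A ROI is addressed by its origin (top-left pixel, 1-based) and size.
#' The default 30 x 30 px ROI at 30 nm/px covers 0.81 um^2, the
#' conventional single-bouton analysis window.
#'
#' @param origin integer (row, col) of the top-left pixel.
#' @param height,width ROI size in pixels.
#' @return an object of class `roi`.
#' @export
roi <- function(origin, height = 30, width = 30) {
  stopifnot(length(origin) == 2, all(origin >= 1),
            height >= 1, width >= 1)
  structure(
    list(origin = as.integer(round(origin)),
         height = as.integer(height), width = as.integer(width)),
    class = "roi"
  )
}

#' Centered ROI helper
#'
#' @param center (row, col) pixel around which the ROI is centered.
#' @param size side length in pixels (square ROI).
#' @return an object of class `roi`.
#' @export
roi_around <- function(center, size = 30) {
  half <- (size - 1) / 2
  roi(origin = round(center - half), height = size, width = size)
}

roi_indices <- function(r, image) {
  rows <- r$origin[1] + seq_len(r$height) - 1L
  cols <- r$origin[2] + seq_len(r$width) - 1L
  if (min(rows) < 1 || max(rows) > nrow(image) ||
      min(cols) < 1 || max(cols) > ncol(image)) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Write a two-channel field as a multi-page 32-bit TIFF
#'
#' Intensities are stored scaled into `[0, 1]`; the common scale factor is
#' recorded in the TIFF description tag so [read_field()] restores the
#' original photon-count scale.
#'
#' @param field a [two_channel_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "two_channel_field"))
  mx <- max(field$reference, field$query, 1e-12)
  desc <- sprintf("endoquant_field;scale=%.17g;pixel_size=%.17g",
                  mx, field$pixel_size)
  tiff::writeTIFF(
    list(field$reference / mx, field$query / mx),
    path, bits.per.sample = 32, compression = "none", description = desc
  )
  invisible(path)
}

#' Read a two-channel field written by [write_field()]
#'
#' @param path TIFF file path.
#' @param pixel_size override for the pixel size; defaults to the value
#'   recorded in the file.
#' @return a [two_channel_field()].
#' @export
read_field <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF", call. = FALSE)
  desc <- attr(pages[[1]], "description")
  scale <- 1; px <- pixel_size
  if (!is.null(desc) && grepl("endoquant_field", desc)) {
    fields <- strsplit(desc, ";")[[1]]
    get_num <- function(key) {
      hit <- grep(paste0("^", key, "="), fields, value = TRUE)
      if (length(hit)) as.numeric(sub(paste0("^", key, "="), "", hit[1])) else NA
    }
    scale <- get_num("scale")
    if (is.null(px)) px <- get_num("pixel_size")
  }
  if (is.null(px) || is.na(px)) {
    stop("pixel_size not recorded in file; supply it explicitly",
         call. = FALSE)
  }
  two_channel_field(pages[[1]] * scale, pages[[2]] * scale, px)
}
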