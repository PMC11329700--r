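# Segmentation of the reference channel: local-maxima calling and
# sub-pixel half-maximum iso-contour extraction.

# background level and spread from the dimmest decile of a region: robust
# to the bright minority of pixels occupied by structures
local_background <- function(values) {
  q <- quantile(values, 0.10, names = FALSE)
  low <- values[values <= q]
  list(level = median(low), sd = max(sd(low), 0))
}

#' Find local intensity maxima
#'
#' Calls pixels that are strictly greater than all 8 neighbours, lie above
#' a prominence floor over the local background, and are mutually separated
#' by at least `min_separation` pixels (greedy suppression, brightest
#' first). Intensity plateaus are never maxima, so a constant image yields
#' an empty result.
#'
#' @param image 2-D numeric matrix.
#' @param roi optional [roi()]; when given, only maxima inside the ROI are
#'   returned and the background is estimated from the ROI.
#' @param min_separation minimum Euclidean distance between accepted
#'   maxima, in pixels.
#' @param min_prominence required height above the local background.
#'   Default: 3 x the background SD (dimmest-decile estimate).
#' @return data.frame with columns `row`, `col`, `intensity`, sorted by
#'   decreasing intensity; coordinates are in the full-image frame.
#' @export
find_local_maxima <- function(image, roi = NULL, min_separation = 3,
                              min_prominence = NULL) {
  stop_if_not_image(image)
  if (!is.null(roi)) {
    idx <- roi_indices(roi, image)
    sub <- image[idx$rows, idx$cols, drop = FALSE]
    off <- c(idx$rows[1] - 1L, idx$cols[1] - 1L)
  } else {
    sub <- image
    off <- c(0L, 0L)
  }
  if (length(sub) == 0) stop("empty ROI", call. = FALSE)
  bg <- local_background(sub)
  if (is.null(min_prominence)) min_prominence <- 3 * bg$sd
  floor_level <- bg$level + min_prominence

  nr <- nrow(sub); nc <- ncol(sub)
  if (nr < 3 || nc < 3) {
    return(data.frame(row = integer(), col = integer(),
                      intensity = numeric()))
  }
  core <- sub[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  is_max <- core > floor_level
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- sub[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc), drop = FALSE]
    is_max <- is_max & (core > nb)
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(data.frame(row = integer(), col = integer(),
                      intensity = numeric()))
  }
  hits <- hits + 1L  # core frame -> sub frame
  vals <- sub[hits]
  ord <- order(vals, decreasing = TRUE)
  hits <- hits[ord, , drop = FALSE]
  vals <- vals[ord]

  keep <- logical(length(vals))
  for (i in seq_along(vals)) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    kept <- hits[keep, , drop = FALSE]
    d2 <- (kept[, 1] - hits[i, 1])^2 + (kept[, 2] - hits[i, 2])^2
    if (all(d2 >= min_separation^2)) keep[i] <- TRUE
  }
  data.frame(
    row = hits[keep, 1] + off[1],
    col = hits[keep, 2] + off[2],
    intensity = vals[keep]
  )
}

#' Extract the half-maximum boundary around a local maximum
#'
#' Traces the sub-pixel iso-contour at half of the maximum's intensity
#' above the local background (level = background + 0.5 x (peak -
#' background)), by linear interpolation between pixel centers. Among the
#' closed contours at that level which enclose the seed maximum, the
#' innermost (smallest-area) one is returned. If no closed enclosing
#' contour exists within the analysed region, the structure is truncated
#' by the region edge and a classed error
#' (`endoquant_edge_truncated`) is thrown so callers can exclude it.
#'
#' @param image 2-D numeric matrix.
#' @param maximum numeric (row, col) of a called local maximum.
#' @param roi optional [roi()] restricting the analysis (and the
#'   background estimate) to a sub-region.
#' @param background background level; estimated from the dimmest decile
#'   of the region when `NULL`.
#' @return object of class `halfmax_boundary`: list with `contour` (closed
#'   matrix of sub-pixel (row, col) points, first row = last row),
#'   `seed` (the maximum), and `level` (the contour intensity).
#' @export
extract_half_max_boundary <- function(image, maximum, roi = NULL,
                                      background = NULL) {
  stop_if_not_image(image)
  maximum <- as.numeric(maximum)
  stopifnot(length(maximum) == 2)
  if (!is.null(roi)) {
    idx <- roi_indices(roi, image)
    sub <- image[idx$rows, idx$cols, drop = FALSE]
    rows <- idx$rows; cols <- idx$cols
  } else {
    sub <- image
    rows <- seq_len(nrow(image)); cols <- seq_len(ncol(image))
  }
  mr <- round(maximum[1]); mc <- round(maximum[2])
  if (!(mr %in% rows) || !(mc %in% cols)) {
    stop("maximum lies outside the analysed region", call. = FALSE)
  }
  if (is.null(background)) background <- local_background(sub)$level
  peak <- image[mr, mc]
  if (peak <= background) {
    stop("maximum is not above background; no half-max level exists",
         call. = FALSE)
  }
  level <- background + 0.5 * (peak - background)

  cl <- contourLines(x = rows, y = cols, z = sub, levels = level)
  enclosing <- list()
  for (cc in cl) {
    n <- length(cc$x)
    closed <- n >= 4 && cc$x[1] == cc$x[n] && cc$y[1] == cc$y[n]
    if (!closed) next
    contour <- cbind(row = cc$x, col = cc$y)
    if (point_in_polygon(c(maximum[1], maximum[2]), contour)) {
      enclosing[[length(enclosing) + 1L]] <- contour
    }
  }
  if (length(enclosing) == 0) {
    stop(structure(
      class = c("endoquant_edge_truncated", "error", "condition"),
      list(message = sprintf(
        "half-max contour around (%d, %d) is truncated by the region edge",
        mr, mc), call = NULL)
    ))
  }
  areas <- vapply(enclosing, function(ct) abs(polygon_area(ct)), numeric(1))
  contour <- enclosing[[which.min(areas)]]
  structure(
    list(contour = contour, seed = c(mr, mc), level = level),
    class = "halfmax_boundary"
  )
}

#' @export
print.halfmax_boundary <- function(x, ...) {
  cat(sprintf(
    "<halfmax_boundary> %d vertices at level %.3g, seed (%d, %d)\n",
    nrow(x$contour) - 1L, x$level, x$seed[1], x$seed[2]
  ))
  invisible(x)
}
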