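# Signed punctum-to-boundary distances and colocalization summaries.

#' Signed distance from a punctum to a half-maximum boundary
#'
#' The unsigned distance is the minimum Euclidean distance from the punctum
#' to any segment of the closed contour polyline, converted to nm through
#' the pixel size. The sign is negative when the punctum lies inside the
#' polygon (by winding number): negative distances mean the punctum sits
#' inside the reference boundary.
#'
#' @param punctum numeric (row, col), in pixels.
#' @param boundary a `halfmax_boundary` (or a closed (row, col) contour
#'   matrix).
#' @param pixel_size nm/px.
#' @param boundary_id optional identifier copied into the record.
#' @return one-row data.frame with columns `row`, `col`, `boundary_id`,
#'   `distance_nm`, `inside`.
#' @export
signed_distance <- function(punctum, boundary, pixel_size,
                            boundary_id = NA_integer_) {
  punctum <- as.numeric(punctum)
  stopifnot(length(punctum) == 2, pixel_size > 0)
  contour <- if (inherits(boundary, "halfmax_boundary")) {
    boundary$contour
  } else {
    as.matrix(boundary)
  }
  if (nrow(unique(contour)) < 3) {
    stop("degenerate contour: fewer than 3 distinct vertices",
         call. = FALSE)
  }
  n <- nrow(contour)
  gap <- max(abs(contour[1, ] - contour[n, ]))
  if (gap > 1e-6) {
    stop("contour must be closed (first point = last point)", call. = FALSE)
  }
  contour[n, ] <- contour[1, ]
  d_px <- point_polyline_distance(punctum, contour)
  inside <- d_px > 0 && point_in_polygon(punctum, contour)
  data.frame(
    row = punctum[1], col = punctum[2],
    boundary_id = boundary_id,
    distance_nm = (if (inside) -1 else 1) * d_px * pixel_size,
    inside = inside
  )
}

#' Colocalization summary over a set of distance records
#'
#' @param records data.frame of [signed_distance()] records (one per query
#'   punctum), with columns `distance_nm` and `boundary_id`.
#' @param n_boundaries total number of reference boundaries analysed
#'   (including those with no punctum); defaults to the number of distinct
#'   `boundary_id`s in `records`.
#' @return list with `fraction_puncta_within` (fraction of puncta with
#'   distance <= 0), `fraction_boundaries_occupied` (fraction of reference
#'   boundaries containing at least one punctum), `ecdf` (empirical CDF of
#'   signed distances, nm), and `n_puncta`.
#' @export
colocalization_summary <- function(records, n_boundaries = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a nonempty data.frame of distance records",
         call. = FALSE)
  }
  stopifnot("distance_nm" %in% names(records))
  if (is.null(n_boundaries)) {
    n_boundaries <- length(unique(records$boundary_id[
      !is.na(records$boundary_id)]))
  }
  inside <- records$distance_nm <= 0
  occupied <- unique(records$boundary_id[inside & !is.na(records$boundary_id)])
  list(
    fraction_puncta_within = mean(inside),
    fraction_boundaries_occupied =
      if (n_boundaries > 0) length(occupied) / n_boundaries else NA_real_,
    ecdf = stats::ecdf(records$distance_nm),
    n_puncta = nrow(records)
  )
}

#' Two-channel STED distance pipeline
#'
#' Runs the full quantification chain on a [two_channel_field()]: Gaussian
#' denoising of both channels, optional blind Richardson-Lucy
#' deconvolution, then per ROI: the brightest reference-channel maximum is
#' segmented by its half-maximum boundary and every query-channel punctum
#' in the ROI is assigned its signed distance to that boundary. ROIs whose
#' boundary is truncated by the ROI edge are excluded and logged.
#'
#' @param field a [two_channel_field()].
#' @param roi_centers matrix/data.frame of (row, col) ROI centers (one
#'   bouton each).
#' @param roi_size ROI side length in pixels.
#' @param denoise_radius Gaussian denoising sigma in pixels.
#' @param deconvolve logical; run blind deconvolution on both channels.
#' @param psf_init initial PSF for deconvolution; default Gaussian of
#'   `psf_sigma`.
#' @param psf_sigma sigma (px) of the default initial PSF.
#' @param iterations,rounds passed to [blind_deconvolve()].
#' @param min_separation passed to [find_local_maxima()].
#' @param min_prominence prominence floor passed to [find_local_maxima()];
#'   by default each ROI uses `prominence_frac` of its own peak height
#'   above background, which stays meaningful after deconvolution (which
#'   compresses the background and would defeat a noise-based floor).
#' @param prominence_frac fraction of the ROI peak height used for the
#'   default prominence floor.
#' @param max_puncta_per_roi cap on query puncta analysed per ROI
#'   (brightest first).
#' @return list with `records` (data.frame of signed distances, one row
#'   per punctum), `summary` (from [colocalization_summary()], `NULL` when
#'   no punctum survived), and `excluded` (data.frame of roi index and
#'   reason).
#' @export
sted_distances <- function(field, roi_centers, roi_size = 30,
                           denoise_radius = 1.2, deconvolve = TRUE,
                           psf_init = NULL, psf_sigma = 1,
                           iterations = 10, rounds = 2,
                           min_separation = 3, min_prominence = NULL,
                           prominence_frac = 0.2,
                           max_puncta_per_roi = Inf) {
  stopifnot(inherits(field, "two_channel_field"))
  roi_centers <- as.matrix(roi_centers)
  stopifnot(ncol(roi_centers) == 2)

  # FFT round-off can leave denoised zeros at ~ -1e-16; clamp before the
  # multiplicative deconvolution updates
  ref <- pmax(gaussian_denoise(field$reference, denoise_radius), 0)
  qry <- pmax(gaussian_denoise(field$query, denoise_radius), 0)
  if (deconvolve) {
    if (is.null(psf_init)) psf_init <- gaussian_psf(psf_sigma)
    dec <- blind_deconvolve(ref, psf_init, iterations, rounds)
    ref <- dec$image
    qry <- blind_deconvolve(qry, dec$psf, iterations, rounds = 1)$image
  }

  records <- list()
  excluded <- list()
  for (i in seq_len(nrow(roi_centers))) {
    r <- roi_around(roi_centers[i, ], roi_size)
    res <- tryCatch({
      prom <- function(img) {
        if (!is.null(min_prominence)) return(min_prominence)
        idx <- roi_indices(r, img)
        sub <- img[idx$rows, idx$cols]
        bg <- local_background(sub)$level
        prominence_frac * (max(sub) - bg)
      }
      ref_max <- find_local_maxima(ref, r, min_separation, prom(ref))
      if (nrow(ref_max) == 0) stop("no reference maximum in ROI",
                                   call. = FALSE)
      bnd <- extract_half_max_boundary(
        ref, c(ref_max$row[1], ref_max$col[1]), roi = r)
      pts <- find_local_maxima(qry, r, min_separation, prom(qry))
      if (nrow(pts) == 0) stop("no query punctum in ROI", call. = FALSE)
      pts <- head(pts, max_puncta_per_roi)
      do.call(rbind, lapply(seq_len(nrow(pts)), function(j) {
        rec <- signed_distance(c(pts$row[j], pts$col[j]), bnd,
                               field$pixel_size, boundary_id = i)
        rec$roi <- i
        rec
      }))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(roi = i, reason = conditionMessage(res))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(row = numeric(), col = numeric(),
               boundary_id = integer(), distance_nm = numeric(),
               inside = logical(), roi = integer())
  list(
    records = records,
    summary = if (nrow(records) > 0) {
      colocalization_summary(records, n_boundaries = nrow(roi_centers))
    } else NULL,
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(roi = integer(), reason = character())
  )
}
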