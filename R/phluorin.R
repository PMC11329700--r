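# pHluorin endocytosis kinetics: rolling-ball background subtraction,
# ROI trace extraction, bleach correction, normalization, and
# single-exponential decay fitting.

#' Fluorescence trace container
#'
#' @param values per-frame intensities.
#' @param frame_rate acquisition rate, Hz.
#' @param stimulus_frame index of the first stimulated frame; frames
#'   before it are baseline (5 s of baseline at 2 Hz puts the stimulus at
#'   frame 11).
#' @return an object of class `fluor_trace`.
#' @export
fluor_trace <- function(values, frame_rate = 2, stimulus_frame) {
  values <- as.numeric(values)
  stopifnot(all(is.finite(values)), frame_rate > 0,
            stimulus_frame > 1, stimulus_frame <= length(values))
  structure(
    list(values = values, frame_rate = frame_rate,
         stimulus_frame = as.integer(stimulus_frame)),
    class = "fluor_trace"
  )
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf(
    "<fluor_trace> %d frames @ %g Hz (%.1f s), stimulus at frame %d\n",
    length(x$values), x$frame_rate, length(x$values) / x$frame_rate,
    x$stimulus_frame
  ))
  invisible(x)
}

# time of each frame in seconds from imaging start (first frame at t = 0)
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) / trace$frame_rate
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image by
#' a disc of the stated radius (the rolling-ball estimate: every structure
#' too narrow for the ball to enter is removed from the background) and
#' subtracts it, clipping at zero.
#'
#' @param image 2-D numeric matrix.
#' @param ball_radius ball radius in pixels (default 50, the conventional
#'   value for widefield pHluorin movies).
#' @return background-subtracted matrix, everywhere >= 0.
#' @export
subtract_background <- function(image, ball_radius = 50) {
  stop_if_not_image(image)
  stopifnot(ball_radius > 0)
  if (2 * ball_radius + 1 > min(dim(image))) {
    stop("ball radius is too large for the image", call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0, nrow(image), ncol(image)))
  # EBImage grayscale morphology operates on [0, 1]; flat-disc opening
  # commutes with positive affine rescaling, so rescale, open, restore
  scaled <- (image - rng[1]) / (rng[2] - rng[1])
  brush <- EBImage::makeBrush(2 * as.integer(ball_radius) + 1, "disc")
  bg01 <- EBImage::opening(scaled, brush)
  background <- as.matrix(bg01) * (rng[2] - rng[1]) + rng[1]
  pmax(image - background, 0)
}

#' Extract per-ROI mean-intensity traces from an image stack
#'
#' ROIs are discs of the stated physical area; a pixel belongs to the disc
#' when its center lies within the disc radius.
#'
#' @param stack 3-D array (rows x cols x frames).
#' @param roi_centers matrix/data.frame of (row, col) disc centers, px.
#' @param roi_area disc area in um^2 (default 2, a single-bouton ROI).
#' @param pixel_size nm/px.
#' @param frame_rate,stimulus_frame metadata copied onto each trace.
#' @return list of [fluor_trace()] objects, one per ROI.
#' @export
extract_roi_traces <- function(stack, roi_centers, roi_area = 2,
                               pixel_size, frame_rate = 2,
                               stimulus_frame = 11) {
  stopifnot(is.array(stack), length(dim(stack)) == 3,
            roi_area > 0, pixel_size > 0)
  roi_centers <- as.matrix(roi_centers)
  stopifnot(ncol(roi_centers) == 2)
  radius_px <- sqrt(roi_area * 1e6 / pi) / pixel_size
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  lapply(seq_len(nrow(roi_centers)), function(i) {
    ctr <- roi_centers[i, ]
    if (ctr[1] - radius_px < 0.5 || ctr[1] + radius_px > nr + 0.5 ||
        ctr[2] - radius_px < 0.5 || ctr[2] + radius_px > nc + 0.5) {
      stop(sprintf("ROI %d: disc is clipped by the frame edge", i),
           call. = FALSE)
    }
    rows <- which(abs(seq_len(nr) - ctr[1]) <= radius_px)
    cols <- which(abs(seq_len(nc) - ctr[2]) <= radius_px)
    mask <- outer((rows - ctr[1])^2, (cols - ctr[2])^2, "+") <= radius_px^2
    vals <- vapply(seq_len(dim(stack)[3]), function(f) {
      sub <- stack[rows, cols, f]
      mean(sub[mask])
    }, numeric(1))
    fluor_trace(vals, frame_rate, stimulus_frame)
  })
}

#' Estimate the photobleaching rate from a no-stimulation control
#'
#' Least-squares fit of `F(t) = F0 * exp(-K * t)` to a control trace that
#' received no stimulus; `K` is the photobleaching rate constant used by
#' [bleach_correct()].
#'
#' @param control_trace a [fluor_trace()] (or numeric vector with
#'   `frame_rate` attribute-free interpretation at 2 Hz).
#' @return list of class `bleach_model` with elements `K` (1/s) and `F0`.
#' @export
estimate_bleach_rate <- function(control_trace) {
  trace <- as_fluor_trace(control_trace)
  y <- trace$values
  if (any(y <= 0)) {
    stop("control trace must be strictly positive for exponential fitting",
         call. = FALSE)
  }
  t <- trace_times(trace)
  # log-linear start, then nonlinear refinement on the original scale
  lin <- lm(log(y) ~ t)
  start <- list(F0 = exp(coef(lin)[[1]]), K = -coef(lin)[[2]])
  # the log-linear solution is already exact for noiseless exponentials
  # (where the refinement step can stall on a zero-residual start)
  est <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ F0 * exp(-K * t), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    list(K = coef(fit)[["K"]], F0 = coef(fit)[["F0"]])
  }, error = function(e) list(K = start$K, F0 = start$F0))
  structure(est, class = "bleach_model")
}

as_fluor_trace <- function(x, frame_rate = 2, stimulus_frame = NULL) {
  if (inherits(x, "fluor_trace")) return(x)
  if (is.numeric(x)) {
    if (is.null(stimulus_frame)) stimulus_frame <- max(2L, length(x))
    return(fluor_trace(x, frame_rate, stimulus_frame))
  }
  stop("expected a fluor_trace or numeric vector", call. = FALSE)
}

#' Correct a trace for photobleaching
#'
#' Multiplies each sample by `exp(t * K)`, with `t` in seconds from
#' imaging start, undoing an exponential bleaching decay of rate `K`.
#'
#' @param trace a [fluor_trace()].
#' @param model a `bleach_model` from [estimate_bleach_rate()], or a bare
#'   rate constant `K` in 1/s.
#' @return the corrected [fluor_trace()].
#' @export
bleach_correct <- function(trace, model) {
  trace <- as_fluor_trace(trace)
  K <- if (inherits(model, "bleach_model")) model$K else as.numeric(model)
  stopifnot(length(K) == 1, is.finite(K))
  trace$values <- trace$values * exp(trace_times(trace) * K)
  trace
}

#' Normalize a trace between the pre-stimulus frame and the peak
#'
#' `N(t) = (F(t) - F_pre) / (F_peak - F_pre)`, where `F_pre` is the frame
#' immediately before the stimulus and `F_peak` the post-stimulus peak
#' (global maximum within `peak_window_s` of the stimulus). The
#' pre-stimulus frame maps to 0 and the peak to 1; the result is invariant
#' to positive affine rescaling of the input.
#'
#' @param trace a [fluor_trace()].
#' @param peak_window_s window after the stimulus searched for the peak, s.
#' @return the normalized [fluor_trace()], with attribute `peak_frame`.
#' @export
normalize_trace <- function(trace, peak_window_s = 5) {
  trace <- as_fluor_trace(trace)
  pre <- trace$values[trace$stimulus_frame - 1L]
  win <- trace$stimulus_frame:min(
    length(trace$values),
    trace$stimulus_frame + round(peak_window_s * trace$frame_rate))
  peak_frame <- win[which.max(trace$values[win])]
  peak <- trace$values[peak_frame]
  if (peak <= pre) {
    stop("no dynamic range: post-stimulus peak does not exceed baseline",
         call. = FALSE)
  }
  trace$values <- (trace$values - pre) / (peak - pre)
  attr(trace, "peak_frame") <- peak_frame
  trace
}

#' Fit a single-exponential decay to a normalized trace
#'
#' Fits the one-phase decay
#' `N(t) = (Y0 - plateau) * exp(-(t - t_peak) / tau) + plateau` by least
#' squares to the post-peak frames of a [normalize_trace()] output. The
#' initial value `Y0` is a free parameter (close to 1 by construction of
#' the normalization): leaving it free keeps `tau` unbiased when shot
#' noise inflates the detected peak frame. With `plateau = FALSE` the
#' plateau is fixed at 0 (complete recovery). The percent of peak
#' fluorescence remaining is read from the raw normalized sample at the
#' frame nearest `remaining_at_s` seconds from imaging start.
#'
#' @param trace a normalized [fluor_trace()].
#' @param plateau logical; fit a free plateau term (incomplete recovery).
#' @param remaining_at_s time of the %-remaining readout, s.
#' @return list of class `decay_fit`: `tau` (s), `plateau`, `amplitude`,
#'   `percent_remaining`, `peak_frame`, and the `nls` fit object.
#' @export
fit_decay <- function(trace, plateau = TRUE, remaining_at_s = 40) {
  trace <- as_fluor_trace(trace)
  peak_frame <- attr(trace, "peak_frame")
  if (is.null(peak_frame)) {
    win <- trace$stimulus_frame:min(length(trace$values),
                                    trace$stimulus_frame +
                                      round(5 * trace$frame_rate))
    peak_frame <- win[which.max(trace$values[win])]
  }
  t <- trace_times(trace)
  post <- peak_frame:length(trace$values)
  if (length(post) < 5) {
    stop("need at least 5 post-peak frames to fit a decay", call. = FALSE)
  }
  ts <- t[post] - t[peak_frame]
  y <- trace$values[post]

  idx40 <- which.min(abs(t - remaining_at_s))
  # a flat trace carries no decay information: report "no decay" rather
  # than failing on a degenerate least-squares problem
  if (diff(range(y)) < 1e-12) {
    return(structure(
      list(tau = Inf, plateau = y[1], amplitude = 0,
           percent_remaining = 100 * trace$values[idx40],
           remaining_at_s = t[idx40], peak_frame = peak_frame,
           at_bound = FALSE, fit = NULL),
      class = "decay_fit"
    ))
  }

  # initial tau from the 1/e crossing of the smoothed decay
  target <- y[1] - (y[1] - min(y)) * (1 - exp(-1))
  below <- which(y <= target)
  tau0 <- if (length(below)) max(ts[below[1]], 1 / trace$frame_rate) else
    max(ts) / 2
  fit <- tryCatch({
    if (plateau) {
      minpack.lm::nlsLM(
        y ~ (y0 - p) * exp(-ts / tau) + p,
        start = list(tau = tau0, p = max(min(min(y), 0.9), 0), y0 = y[1]),
        lower = c(tau = 1e-6, p = -0.5, y0 = 0),
        upper = c(tau = 1e6, p = 1, y0 = 2),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    } else {
      minpack.lm::nlsLM(
        y ~ y0 * exp(-ts / tau), start = list(tau = tau0, y0 = y[1]),
        lower = c(tau = 1e-6, y0 = 0), upper = c(tau = 1e6, y0 = 2),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    }
  }, error = function(e) {
    stop("decay fit did not converge: ", conditionMessage(e), call. = FALSE)
  })
  cf <- coef(fit)
  tau <- cf[["tau"]]
  p <- if (plateau) cf[["p"]] else 0
  at_bound <- tau <= 1.5e-6 || tau >= 0.9e6
  if (at_bound) {
    warning("fitted tau is at a parameter bound; treat as unreliable")
  }
  idx40 <- which.min(abs(t - remaining_at_s))
  y0 <- cf[["y0"]]
  structure(
    list(
      tau = tau, plateau = p, amplitude = y0 - p,
      percent_remaining = 100 * trace$values[idx40],
      remaining_at_s = t[idx40],
      peak_frame = peak_frame,
      at_bound = at_bound,
      fit = fit
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> tau = %.3g s, plateau = %.3g, %.1f%% remaining at %g s\n",
    x$tau, x$plateau, x$percent_remaining, x$remaining_at_s
  ))
  invisible(x)
}

#' Fit a cohort of traces through the full kinetics chain
#'
#' Convenience wrapper: bleach-correct, normalize and fit each trace;
#' traces that fail (no dynamic range, non-convergence, tau at bound) are
#' excluded and reported.
#'
#' @param traces list of [fluor_trace()] objects.
#' @param bleach_K bleaching rate constant (1/s) or `bleach_model`.
#' @param plateau,remaining_at_s passed to [fit_decay()].
#' @return list with `fits` (data.frame: trace, tau, plateau,
#'   percent_remaining) and `excluded` (data.frame: trace, reason).
#' @export
fit_trace_cohort <- function(traces, bleach_K = 0, plateau = TRUE,
                             remaining_at_s = 40) {
  fits <- list(); excluded <- list()
  for (i in seq_along(traces)) {
    res <- tryCatch({
      tr <- bleach_correct(traces[[i]], bleach_K)
      fd <- fit_decay(normalize_trace(tr), plateau = plateau,
                      remaining_at_s = remaining_at_s)
      if (fd$at_bound) stop("tau at parameter bound", call. = FALSE)
      data.frame(trace = i, tau = fd$tau, plateau = fd$plateau,
                 percent_remaining = fd$percent_remaining)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(trace = i, reason = conditionMessage(res))
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  list(
    fits = if (length(fits)) do.call(rbind, fits) else
      data.frame(trace = integer(), tau = numeric(), plateau = numeric(),
                 percent_remaining = numeric()),
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(trace = integer(), reason = character())
  )
}
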