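# Internal numerical helpers shared across modules: seeded evaluation,
# Gaussian kernels, 2-D convolution with reflective padding, and basic
# computational geometry on polylines/polygons.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators are pure
#' functions of their configuration and do not disturb the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Discrete normalized isotropic Gaussian kernel
#'
#' @param sigma standard deviation in pixels.
#' @param radius half-width of the kernel support in pixels; defaults to
#'   `ceiling(4 * sigma)` which captures > 99.99% of the mass.
#' @return a `(2*radius+1)` square matrix summing to 1.
#' @noRd
gaussian_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  ax <- -radius:radius
  g1 <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' Flip a kernel in both dimensions (adjoint of convolution)
#' @noRd
flip2 <- function(k) k[nrow(k):1, ncol(k):1, drop = FALSE]

#' Pad a matrix by reflection
#' @noRd
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(pr < nr, pc < nc)
  ri <- c(rev(seq_len(pr) + 1L), seq_len(nr), nr - seq_len(pr))
  ci <- c(rev(seq_len(pc) + 1L), seq_len(nc), nc - seq_len(pc))
  m[ri, ci, drop = FALSE]
}

#' Same-size 2-D convolution with reflective boundary handling
#'
#' FFT-based circular convolution on a reflectively padded copy, cropped back
#' to the input size. Reflective padding keeps constants exactly constant and
#' conserves total intensity of compact objects.
#' @noRd
conv2_same <- function(img, kern) {
  stopifnot(is.matrix(img), is.matrix(kern))
  kr <- nrow(kern); kc <- ncol(kern)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  if (pr == 0 && pc == 0) return(img * kern[1, 1])
  p <- pad_reflect(img, pr, pc)
  nr <- nrow(p); nc <- ncol(p)
  # embed kernel with its center at index (1, 1), wrapping negative offsets
  kp <- matrix(0, nr, nc)
  ri <- ((-pr:pr) %% nr) + 1L
  ci <- ((-pc:pc) %% nc) + 1L
  kp[ri, ci] <- kern
  out <- Re(fft(fft(p) * fft(kp), inverse = TRUE)) / (nr * nc)
  out[pr + seq_len(nrow(img)), pc + seq_len(ncol(img)), drop = FALSE]
}

#' Minimum distance from a point to a closed polyline, in polyline units
#'
#' @param p numeric length-2 point (row, col).
#' @param contour matrix with columns (row, col); closed (first row = last).
#' @return minimum Euclidean point-to-segment distance.
#' @noRd
point_polyline_distance <- function(p, contour) {
  a <- contour[-nrow(contour), , drop = FALSE]
  b <- contour[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  t <- rowSums(ap * ab) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  min(sqrt((p[1] - proj[, 1])^2 + (p[2] - proj[, 2])^2))
}

#' Winding-number point-in-polygon test
#'
#' Nonzero winding number means inside. The polygon is given as a closed
#' matrix of (row, col) vertices.
#' @noRd
point_in_polygon <- function(p, contour) {
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x)
  wn <- 0L
  for (i in seq_len(n - 1L)) {
    is_left <- (x[i + 1L] - x[i]) * (p[2] - y[i]) -
      (p[1] - x[i]) * (y[i + 1L] - y[i])
    if (y[i] <= p[2]) {
      if (y[i + 1L] > p[2] && is_left > 0) wn <- wn + 1L
    } else {
      if (y[i + 1L] <= p[2] && is_left < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

#' Signed area of a closed polygon (shoelace); magnitude only is used
#' @noRd
polygon_area <- function(contour) {
  x <- contour[, 1]; y <- contour[, 2]
  n <- nrow(contour)
  0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
}

stop_if_not_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a 2-D numeric matrix", arg), call. = FALSE)
  }
}
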