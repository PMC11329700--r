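# Independent oracles used across tests. These deliberately use different
# algorithms (scalar loops, ray casting, direct summation) from the
# package implementation (vectorized projections, winding numbers, FFT).

# even-odd ray-casting point-in-polygon test (horizontal ray, +col)
oracle_inside <- function(p, contour) {
  n <- nrow(contour)
  crossings <- 0L
  for (i in seq_len(n - 1L)) {
    y1 <- contour[i, 1]; x1 <- contour[i, 2]
    y2 <- contour[i + 1L, 1]; x2 <- contour[i + 1L, 2]
    if ((y1 > p[1]) != (y2 > p[1])) {
      x_at <- x1 + (p[1] - y1) / (y2 - y1) * (x2 - x1)
      if (x_at > p[2]) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# brute-force minimum distance: resample the contour to n_points along its
# arc (keeping every original vertex) and take the scalar per-segment
# minimum over the resampled polyline
oracle_min_distance <- function(p, contour, n_points = 10000) {
  seg_len <- sqrt(rowSums(diff(contour)^2))
  pts <- list(contour[1, , drop = FALSE])
  for (i in seq_along(seg_len)) {
    k <- max(2L, ceiling(n_points * seg_len[i] / sum(seg_len)))
    t <- seq(0, 1, length.out = k)[-1]
    pts[[i + 1L]] <- cbind(
      contour[i, 1] + t * (contour[i + 1L, 1] - contour[i, 1]),
      contour[i, 2] + t * (contour[i + 1L, 2] - contour[i, 2])
    )
  }
  dense <- do.call(rbind, pts)
  best <- Inf
  for (i in seq_len(nrow(dense) - 1L)) {
    a <- dense[i, ]; b <- dense[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best) best <- d
  }
  best
}

# direct O(N^2 k^2) convolution with reflective padding
oracle_convolve <- function(img, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    acc <- 0
    for (dr in -pr:pr) for (dc in -pc:pc) {
      rr <- reflect(r - dr, nrow(img))
      cc <- reflect(c - dc, ncol(img))
      acc <- acc + img[rr, cc] * kern[dr + pr + 1L, dc + pc + 1L]
    }
    out[r, c] <- acc
  }
  out
}

# analytic 2-D Gaussian blob on a pixel grid (distinct from the package
# internal: written directly here)
blob <- function(nr, nc, center, sigma, amplitude = 1) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  amplitude * exp(-((r - center[1])^2 + (c - center[2])^2) / (2 * sigma^2))
}

# smooth star-shaped closed contour around a center, for random geometry
random_contour <- function(center, r0, wobble = 0.3, lobes = NULL,
                           n = 120) {
  if (is.null(lobes)) lobes <- sample(2:5, 1)
  phase <- runif(1, 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n + 1)
  rad <- r0 * (1 + wobble * sin(lobes * th + phase))
  ct <- cbind(center[1] + rad * cos(th), center[2] + rad * sin(th))
  ct[n + 1, ] <- ct[1, ]
  ct
}
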