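#' Simulate a two-channel STED field with known punctum offsets
#'
#' Lays synthetic boutons on a grid. The reference channel holds one
#' Gaussian blob per synapse (the active-zone / cluster proxy); the query
#' channel holds one point punctum per synapse, placed at the stated signed
#' radial offset from the blob's analytic half-maximum circle (radius
#' `boundary_sigma * sqrt(2*log(2))`; negative offsets are inside). Both
#' channels are convolved with a Gaussian PSF — carried out analytically,
#' so the pre-noise image equals the object-model integral exactly — and
#' then Poisson-sampled at the requested photon budget.
#'
#' @param config a [sim_config()].
#' @param n_synapses number of boutons.
#' @param boundary_sigma Gaussian sigma of the reference blob, px.
#' @param punctum_offsets signed offsets (nm) from the half-max circle;
#'   recycled over synapses. Negative = inside the boundary.
#' @param psf_sigma Gaussian PSF sigma, px.
#' @param photon_budget expected photons per object (blob or punctum);
#'   `Inf` disables Poisson sampling (zero-noise limit).
#' @param background expected background photons per pixel.
#' @param tile tile side length per synapse, px.
#' @return list with `field` (a [two_channel_field()]) and `truth`
#'   (data.frame: synapse, blob center, punctum position, offset_nm,
#'   halfmax_radius_px, and the ROI center to analyse).
#' @examples
#' sim <- gen_sted_field(sim_config(1), n_synapses = 4,
#'                       punctum_offsets = c(-60, 0, 60, 120))
#' sim$truth$offset_nm
#' @export
gen_sted_field <- function(config, n_synapses,
                           boundary_sigma = 4,
                           punctum_offsets = 0,
                           psf_sigma = 1,
                           photon_budget = 1e4,
                           background = 2,
                           tile = 41) {
  config <- as_sim_config(config)
  stopifnot(n_synapses >= 1, boundary_sigma > 0, psf_sigma > 0,
            all(is.finite(punctum_offsets)), photon_budget > 0,
            background >= 0, tile >= 15)
  offsets <- rep_len(punctum_offsets, n_synapses)

  ncols <- ceiling(sqrt(n_synapses))
  nrows <- ceiling(n_synapses / ncols)
  img_r <- nrows * tile
  img_c <- ncols * tile
  r_half <- boundary_sigma * sqrt(2 * log(2))

  # zero-noise limit: keep the same expected-photon image, skip sampling
  budget <- if (is.finite(photon_budget)) photon_budget else 1e6

  with_seed(config$seed, {
    ref <- matrix(background, img_r, img_c)
    qry <- matrix(background, img_r, img_c)
    truth <- vector("list", n_synapses)
    # image of the blob after PSF: Gaussian with combined variance
    sig_ref <- sqrt(boundary_sigma^2 + psf_sigma^2)
    for (i in seq_len(n_synapses)) {
      tr <- ((i - 1) %/% ncols)
      tc <- ((i - 1) %% ncols)
      center <- c(tr * tile + (tile + 1) / 2, tc * tile + (tile + 1) / 2) +
        runif(2, -0.5, 0.5)
      angle <- runif(1, 0, 2 * pi)
      rad_px <- r_half + offsets[i] / config$pixel_size
      if (rad_px < 0) {
        stop(sprintf(
          "synapse %d: offset %g nm places the punctum at negative radius",
          i, offsets[i]), call. = FALSE)
      }
      punctum <- center + rad_px * c(cos(angle), sin(angle))
      if (punctum[1] < 1 || punctum[1] > img_r ||
          punctum[2] < 1 || punctum[2] > img_c) {
        stop(sprintf(
          "synapse %d: offset %g nm places the punctum outside the image",
          i, offsets[i]), call. = FALSE)
      }
      ref <- ref + gauss2d(img_r, img_c, center, sig_ref, budget)
      qry <- qry + gauss2d(img_r, img_c, punctum, psf_sigma, budget)
      truth[[i]] <- data.frame(
        synapse = i,
        center_row = center[1], center_col = center[2],
        punctum_row = punctum[1], punctum_col = punctum[2],
        offset_nm = offsets[i],
        halfmax_radius_px = r_half,
        roi_row = round(center[1]), roi_col = round(center[2])
      )
    }
    if (is.finite(photon_budget)) {
      ref <- matrix(rpois(length(ref), ref), img_r, img_c)
      qry <- matrix(rpois(length(qry), qry), img_r, img_c)
    }
    list(
      field = two_channel_field(ref, qry, config$pixel_size),
      truth = do.call(rbind, truth)
    )
  })
}

# 2-D Gaussian with total mass `total`, centered at sub-pixel (row, col)
gauss2d <- function(nr, nc, center, sigma, total) {
  gr <- exp(-((seq_len(nr) - center[1])^2) / (2 * sigma^2))
  gc <- exp(-((seq_len(nc) - center[2])^2) / (2 * sigma^2))
  amp <- total / (2 * pi * sigma^2)
  amp * outer(gr, gc)
}
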