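#' Simulate annotated EM synaptic profiles with known morphometry
#'
#' Builds [profile_annotation()] objects with a plasma-membrane polyline,
#' a postsynaptic-density segment, endocytic pits and vesicular traces.
#' Pit traces are circular arcs with exact analytic base width and depth
#' (depth <= width/2 gives a shallow U, depth > width/2 an Omega profile
#' with a constricted neck), randomly rotated and translated, so the
#' generated geometry round-trips exactly through [pit_geometry()].
#' Vesicles and endosomes are circle traces of exact diameter.
#'
#' @param config a [sim_config()].
#' @param counts data.frame with one row per profile group: columns
#'   `condition`, `time`, `n_profiles`, `pits`, `svs`, `levs`,
#'   `endosomes` (exact per-profile counts; ferritin-positive for the
#'   vesicular classes).
#' @param pit_shapes list of `c(width, depth)` pairs in nm, cycled over
#'   the generated pits.
#' @param sv_diameters,lev_diameters,endosome_diameters diameter pools
#'   (nm) sampled per class; defaults lie strictly inside each class.
#' @param scale nm/px recorded in the annotations.
#' @return list with `profiles` (list of [profile_annotation()]) and
#'   `truth` (list: `counts` data.frame per profile, `pits` data.frame of
#'   true width/depth per pit).
#' @examples
#' counts <- data.frame(condition = "wt", time = "100ms", n_profiles = 2,
#'                      pits = 1, svs = 2, levs = 1, endosomes = 0)
#' sim <- gen_em_profiles(sim_config(1), counts)
#' count_structures(sim$profiles)
#' @export
gen_em_profiles <- function(config, counts,
                            pit_shapes = list(c(60, 40), c(80, 40)),
                            sv_diameters = c(35, 40, 45, 50),
                            lev_diameters = c(65, 75, 85, 95),
                            endosome_diameters = c(110, 150, 200),
                            scale = 1) {
  config <- as_sim_config(config)
  stopifnot(is.data.frame(counts),
            all(c("condition", "time", "n_profiles", "pits", "svs",
                  "levs", "endosomes") %in% names(counts)),
            all(counts$n_profiles >= 1), scale > 0)
  for (ps in pit_shapes) {
    if (length(ps) != 2 || ps[1] <= 0 || ps[2] < 0) {
      stop("pit shapes must be c(width > 0, depth >= 0) in nm",
           call. = FALSE)
    }
  }
  stopifnot(all(sv_diameters > 0, sv_diameters < 60),
            all(lev_diameters >= 60, lev_diameters <= 100),
            all(endosome_diameters > 100))

  with_seed(config$seed, {
    profiles <- list(); truth_counts <- list(); truth_pits <- list()
    pit_i <- 0L; pid <- 0L
    for (g in seq_len(nrow(counts))) {
      row <- counts[g, ]
      for (k in seq_len(row$n_profiles)) {
        pid <- pid + 1L
        id <- sprintf("%s_%s_p%02d", row$condition, row$time, k)
        feats <- list(membrane_features())
        obj <- 2L
        for (j in seq_len(row$pits)) {
          pit_i <- pit_i + 1L
          shape <- pit_shapes[[(pit_i - 1L) %% length(pit_shapes) + 1L]]
          feats[[length(feats) + 1L]] <- pit_feature(
            obj, shape[1], shape[2],
            angle = runif(1, 0, 2 * pi),
            origin = runif(2, -500, 500))
          truth_pits[[length(truth_pits) + 1L]] <- data.frame(
            profile_id = id, object = obj,
            width = shape[1], depth = shape[2])
          obj <- obj + 1L
        }
        place <- function(n, pool, feature) {
          out <- list()
          for (j in seq_len(n)) {
            d <- pool[sample.int(length(pool), 1)]
            out[[j]] <- circle_feature(
              obj <<- obj + 1L, feature, d,
              center = runif(2, -500, 500), ferritin = TRUE)
          }
          out
        }
        feats <- c(feats,
                   place(row$svs, sv_diameters, "synaptic_vesicles"),
                   place(row$levs, lev_diameters, "large_vesicles"),
                   place(row$endosomes, endosome_diameters, "endosomes"))
        features <- do.call(rbind, feats)
        profiles[[pid]] <- profile_annotation(
          id, scale, features, condition = row$condition, time = row$time)
        truth_counts[[pid]] <- data.frame(
          profile_id = id, condition = row$condition, time = row$time,
          pits = row$pits, svs = row$svs, levs = row$levs,
          endosomes = row$endosomes)
      }
    }
    list(
      profiles = profiles,
      truth = list(
        counts = do.call(rbind, truth_counts),
        pits = if (length(truth_pits)) do.call(rbind, truth_pits) else
          data.frame(profile_id = character(), object = integer(),
                     width = numeric(), depth = numeric())
      )
    )
  })
}

# gently curved membrane polyline with a short PSD segment
membrane_features <- function() {
  x <- seq(-600, 600, by = 60)
  mem <- data.frame(feature = "plasma_membrane", object = 1L,
                    x = x, y = 0.0002 * x^2, ferritin = FALSE)
  psd <- data.frame(feature = "postsynaptic_density", object = 1L,
                    x = seq(-100, 100, by = 50),
                    y = -40 + 0.0002 * seq(-100, 100, by = 50)^2,
                    ferritin = FALSE)
  rbind(mem, psd)
}

# open circular-arc pit trace: endpoints span the base chord `width`
# apart, the arc apex sits `depth` from the chord; rigid motion applied
pit_feature <- function(object, width, depth, angle = 0,
                        origin = c(0, 0), n_points = 41) {
  if (depth == 0) {
    local <- cbind(x = seq(-width / 2, width / 2, length.out = 3),
                   y = c(0, 0, 0))
  } else {
    radius <- (width^2 / 4 + depth^2) / (2 * depth)
    cy <- depth - radius
    # endpoint angles measured at the circle center; go through the apex
    a0 <- atan2(0 - cy, -width / 2)
    a1 <- atan2(0 - cy, width / 2)
    if (a1 > a0) a1 <- a1 - 2 * pi   # sweep downward through pi/2 apex
    th <- seq(a0, a1, length.out = n_points)
    local <- cbind(x = radius * cos(th), y = cy + radius * sin(th))
  }
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- local %*% t(rot)
  data.frame(feature = "pits", object = object,
             x = xy[, 1] + origin[1], y = xy[, 2] + origin[2],
             ferritin = FALSE)
}

# closed circle trace of exact diameter
circle_feature <- function(object, feature, diameter, center = c(0, 0),
                           ferritin = FALSE, n_points = 24) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  data.frame(feature = feature, object = object,
             x = center[1] + diameter / 2 * cos(th),
             y = center[2] + diameter / 2 * sin(th),
             ferritin = ferritin)
}
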