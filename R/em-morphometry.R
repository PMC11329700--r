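# Flash-and-freeze EM synapse morphometry from annotated coordinate
# traces: annotation IO, vesicle classification, pit geometry, structure
# counts, and stimulus-evoked time-course summaries.

em_feature_vocabulary <- c(
  "plasma_membrane", "postsynaptic_density",
  "synaptic_vesicles", "large_vesicles", "endosomes", "pits"
)

#' EM profile annotation container
#'
#' Named coordinate traces recorded on one synaptic profile. Coordinates
#' are held in nm; `scale` records the nm/px factor of the source
#' micrograph for round-tripping the on-disk pixel coordinates.
#'
#' @param profile_id identifier.
#' @param scale nm/px of the annotated micrograph.
#' @param features data.frame with columns `feature` (one of
#'   plasma_membrane, postsynaptic_density, synaptic_vesicles,
#'   large_vesicles, endosomes, pits), `object` (trace id within feature),
#'   `x`, `y` (nm), `ferritin` (logical flag, vesicular features only).
#' @param condition,time optional experimental labels.
#' @return an object of class `profile_annotation`.
#' @export
profile_annotation <- function(profile_id, scale, features,
                               condition = NA_character_, time = NA) {
  stopifnot(length(scale) == 1, scale > 0, is.data.frame(features))
  needed <- c("feature", "object", "x", "y", "ferritin")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    stop("features table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(features$feature), em_feature_vocabulary)
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pit_rows <- features$feature == "pits"
  if (any(pit_rows)) {
    sizes <- table(features$object[pit_rows])
    if (any(sizes < 3)) {
      stop("every pit trace needs at least 3 points", call. = FALSE)
    }
  }
  structure(
    list(profile_id = profile_id, scale = as.numeric(scale),
         condition = condition, time = time,
         features = features[, needed]),
    class = "profile_annotation"
  )
}

#' @export
print.profile_annotation <- function(x, ...) {
  tab <- table(x$features$feature[!duplicated(
    paste(x$features$feature, x$features$object))])
  cat(sprintf("<profile_annotation> %s (%s, t=%s), scale %g nm/px\n",
              x$profile_id, x$condition, format(x$time), x$scale))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

# extract one feature's traces as a list of (x, y) nm matrices
feature_traces <- function(annotation, feature) {
  f <- annotation$features[annotation$features$feature == feature, ,
                           drop = FALSE]
  if (nrow(f) == 0) return(list())
  lapply(split(f, f$object), function(d) {
    list(xy = cbind(x = d$x, y = d$y), ferritin = d$ferritin[1])
  })
}

#' Write a profile annotation as JSON
#'
#' Coordinates are stored in pixels (nm / scale), mirroring the raw export
#' of an annotation tool; [parse_annotation()] converts back to nm.
#'
#' @param annotation a [profile_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "profile_annotation"))
  f <- annotation$features
  payload <- list(
    profile_id = annotation$profile_id,
    scale_nm_per_px = annotation$scale,
    condition = annotation$condition,
    time = annotation$time,
    features = lapply(split(f, list(f$feature, f$object), drop = TRUE),
                      function(d) {
      list(name = d$feature[1], object = d$object[1],
           ferritin = isTRUE(d$ferritin[1]),
           x_px = d$x / annotation$scale,
           y_px = d$y / annotation$scale)
    })
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Parse a profile-annotation JSON file
#'
#' @param file path written by [write_annotation()] (or conforming to the
#'   same dialect: pixel coordinates plus a `scale_nm_per_px` field).
#' @return a [profile_annotation()] with coordinates in nm.
#' @export
parse_annotation <- function(file) {
  payload <- tryCatch(
    jsonlite::fromJSON(file, simplifyVector = FALSE),
    error = function(e) stop("malformed annotation file: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(payload$scale_nm_per_px)) {
    stop("annotation file lacks the scale_nm_per_px field", call. = FALSE)
  }
  scale <- as.numeric(payload$scale_nm_per_px)
  feats <- lapply(payload$features, function(ft) {
    if (is.null(ft$name) || is.null(ft$x_px) || is.null(ft$y_px)) {
      stop("malformed feature entry in annotation file", call. = FALSE)
    }
    x <- as.numeric(unlist(ft$x_px)); y <- as.numeric(unlist(ft$y_px))
    if (length(x) != length(y)) {
      stop(sprintf("feature %s/%s: x and y lengths differ",
                   ft$name, ft$object), call. = FALSE)
    }
    data.frame(feature = ft$name,
               object = if (is.null(ft$object)) 1L else ft$object,
               x = x * scale, y = y * scale,
               ferritin = isTRUE(ft$ferritin))
  })
  profile_annotation(
    profile_id = payload$profile_id,
    scale = scale,
    features = do.call(rbind, feats),
    condition = if (is.null(payload$condition)) NA_character_ else
      payload$condition,
    time = if (is.null(payload$time)) NA else payload$time
  )
}

#' Classify a vesicular structure by diameter
#'
#' Synaptic vesicles are below 60 nm; large endocytic vesicles span 60 to
#' 100 nm inclusive; circular structures above 100 nm are endosomes
#' (irregular large structures are also scored as endosomes when flagged
#' non-circular, matching their morphological definition).
#'
#' @param diameter nm; vectorized.
#' @param is_circular logical; vectorized.
#' @return character vector: "synaptic_vesicle", "large_vesicle", or
#'   "endosome".
#' @examples
#' classify_vesicle(c(40, 80, 120), TRUE)
#' @export
classify_vesicle <- function(diameter, is_circular = TRUE) {
  stopifnot(all(diameter > 0))
  n <- max(length(diameter), length(is_circular))
  diameter <- rep_len(diameter, n)
  ifelse(diameter < 60, "synaptic_vesicle",
         ifelse(diameter <= 100, "large_vesicle", "endosome"))
}

#' Width and depth of an endocytic pit trace
#'
#' The pit base is the chord joining the two endpoints of the open trace;
#' width is the chord length and depth the maximum perpendicular distance
#' from any trace point to the chord. Both are invariant under rigid
#' motion of the trace.
#'
#' @param pit_trace matrix/data.frame with columns (x, y) in nm; >= 3
#'   points, endpoints marking the pit base.
#' @return list of class `pit_geometry`: `width` (nm), `depth` (nm).
#' @examples
#' theta <- seq(0, pi, length.out = 41)
#' pit_geometry(cbind(40 * cos(theta), 40 * sin(theta)))
#' @export
pit_geometry <- function(pit_trace) {
  xy <- as.matrix(pit_trace)
  stopifnot(ncol(xy) == 2)
  if (nrow(xy) < 3) stop("pit trace needs at least 3 points", call. = FALSE)
  a <- xy[1, ]; b <- xy[nrow(xy), ]
  chord <- b - a
  width <- sqrt(sum(chord^2))
  if (width == 0) {
    stop("coincident trace endpoints: pit base is undefined", call. = FALSE)
  }
  # perpendicular distance of every point to the infinite base line
  rel <- sweep(xy, 2, a)
  depth <- max(abs(rel[, 1] * chord[2] - rel[, 2] * chord[1]) / width)
  structure(list(width = width, depth = depth), class = "pit_geometry")
}

#' @export
print.pit_geometry <- function(x, ...) {
  cat(sprintf("<pit_geometry> width %.1f nm, depth %.1f nm\n",
              x$width, x$depth))
  invisible(x)
}

# measured diameter of a closed vesicle/endosome trace: twice the mean
# vertex distance from the vertex centroid (exact for circles)
trace_diameter <- function(xy) {
  ctr <- colMeans(xy)
  2 * mean(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
}

# circularity (4*pi*A/P^2) of a closed trace; 1 for a circle
trace_circularity <- function(xy) {
  closed <- rbind(xy, xy[1, ])
  area <- abs(polygon_area(closed))
  per <- sum(sqrt(rowSums(diff(closed)^2)))
  if (per == 0) return(0)
  4 * pi * area / per^2
}

#' Per-profile structure counts
#'
#' Counts endocytic pits and, among ferritin-positive vesicular traces,
#' synaptic vesicles, large endocytic vesicles and endosomes, classifying
#' each trace by its measured diameter with [classify_vesicle()]
#' (independent of which feature name the annotator filed it under).
#'
#' @param profiles list of [profile_annotation()] objects (or a single
#'   one).
#' @param circularity_min closed traces with circularity below this are
#'   scored as irregular (non-circular).
#' @return data.frame, one row per profile: `profile_id`, `condition`,
#'   `time`, `pits`, `svs_ferritin`, `levs_ferritin`,
#'   `endosomes_ferritin`.
#' @export
count_structures <- function(profiles, circularity_min = 0.85) {
  if (inherits(profiles, "profile_annotation")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  rows <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "profile_annotation"))
    n_pits <- length(feature_traces(p, "pits"))
    ves <- c(feature_traces(p, "synaptic_vesicles"),
             feature_traces(p, "large_vesicles"),
             feature_traces(p, "endosomes"))
    cls <- c(synaptic_vesicle = 0L, large_vesicle = 0L, endosome = 0L)
    for (v in ves) {
      if (!isTRUE(v$ferritin)) next
      d <- trace_diameter(v$xy)
      circ <- trace_circularity(v$xy) >= circularity_min
      k <- classify_vesicle(d, circ)
      cls[k] <- cls[k] + 1L
    }
    data.frame(
      profile_id = p$profile_id, condition = p$condition,
      time = if (is.null(p$time)) NA else p$time,
      pits = n_pits,
      svs_ferritin = cls[["synaptic_vesicle"]],
      levs_ferritin = cls[["large_vesicle"]],
      endosomes_ferritin = cls[["endosome"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Time-course summary of structure counts
#'
#' Per condition, time point and structure class: mean count per synaptic
#' profile, SEM (`sd/sqrt(n)`, `NA` for single-profile groups), n, and the
#' stimulus-evoked increase (group mean minus the same condition's
#' unstimulated mean).
#'
#' @param counts data.frame from [count_structures()] with `condition` and
#'   `time` filled in.
#' @param no_stim_label value of `time` identifying the unstimulated
#'   control group.
#' @param classes count columns to summarize.
#' @return data.frame with columns `condition`, `time`, `class`, `n`,
#'   `mean`, `sem`, `increase`.
#' @export
summarize_time_course <- function(counts, no_stim_label = "no_stim",
                                  classes = c("pits", "svs_ferritin",
                                              "levs_ferritin",
                                              "endosomes_ferritin")) {
  stopifnot(is.data.frame(counts), nrow(counts) >= 1,
            all(c("condition", "time") %in% names(counts)),
            all(classes %in% names(counts)))
  out <- list()
  for (cond in unique(counts$condition)) {
    sub <- counts[counts$condition == cond, , drop = FALSE]
    base <- sub[sub$time == no_stim_label, , drop = FALSE]
    if (nrow(base) == 0) {
      stop(sprintf("condition %s has no '%s' group", cond, no_stim_label),
           call. = FALSE)
    }
    for (tp in unique(sub$time)) {
      grp <- sub[sub$time == tp, , drop = FALSE]
      for (cl in classes) {
        v <- grp[[cl]]
        n <- length(v)
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, time = tp, class = cl, n = n,
          mean = mean(v),
          sem = if (n > 1) sd(v) / sqrt(n) else NA_real_,
          increase = mean(v) - mean(base[[cl]])
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
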