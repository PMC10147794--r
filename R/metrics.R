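#' Clinical spine-curvature indices
#'
#' Automated extraction of the standard scoliosis follow-up measurements
#' from a 3D landmark set: frontal-plane Cobb angles, sagittal kyphosis and
#' lordosis, apical axial rotation and per-level vertebral-body wedging.
#' All angles are reported in degrees to 0.1 degree display precision.
#'
#' @name clinical-indices
NULL

# in-plane tilt (deg) of the endplate line of `edge` ("sup"/"inf") at a level.
# frontal plane: line through left/right corners, angle of (left - right)
# measured from the +y axis in (y, z).  sagittal plane: line through
# ant/post corners, angle of (ant - post) from the +x axis in (x, z).
# Zero for a level stack with horizontal endplates; sign follows the
# right-hand sense of the projection plane.
endplate_tilt <- function(lm, level, edge = c("sup", "inf"),
                          plane = c("frontal", "sagittal")) {
  edge <- match.arg(edge)
  plane <- match.arg(plane)
  if (plane == "frontal") {
    a <- landmark_coord(lm, level, paste0(edge, "_left"))
    b <- landmark_coord(lm, level, paste0(edge, "_right"))
    d <- a - b
    rad2deg(atan2(d[3], d[2]))
  } else {
    a <- landmark_coord(lm, level, paste0(edge, "_ant"))
    b <- landmark_coord(lm, level, paste0(edge, "_post"))
    d <- a - b
    rad2deg(atan2(d[3], d[1]))
  }
}

#' Cobb angle with automatic end-vertebra selection
#'
#' The Cobb angle of a curve is the angle between the superior endplate of
#' the upper end vertebra and the inferior endplate of the lower end
#' vertebra. End vertebrae are selected by exhaustive maximization of the
#' inter-endplate angle over all ordered level pairs in `level_range` (the
#' clinical "most tilted vertebrae" rule). The apex is the level between
#' the end vertebrae whose centroid deviates most, laterally, from the
#' chord joining the end-vertebra centroids; the convex side is the side of
#' that deviation.
#'
#' @param lm a `landmark_set` covering `level_range`.
#' @param plane `"frontal"` (default; scoliosis Cobb) or `"sagittal"`.
#' @param level_range character vector of contiguous level labels
#'   (default all 17 present levels).
#' @return List with `angle` (deg, >= 0), `upper_end`, `lower_end`, `apex`
#'   (level labels) and `convex_side` (`"left"`/`"right"`, frontal plane
#'   only; for the sagittal plane the sign convention field is `NA`).
#' @export
cobb_angle <- function(lm, plane = c("frontal", "sagittal"),
                       level_range = NULL) {
  plane <- match.arg(plane)
  if (is.null(level_range)) {
    level_range <- spine_levels()[spine_levels() %in% unique(lm$level)]
  }
  level_range <- spine_levels()[spine_levels() %in% level_range]
  if (length(level_range) < 3) stop("cobb_angle needs at least 3 levels in range")
  n <- length(level_range)
  sup <- vapply(level_range, endplate_tilt, 0, lm = lm, edge = "sup", plane = plane)
  inf <- vapply(level_range, endplate_tilt, 0, lm = lm, edge = "inf", plane = plane)
  best <- c(0, 1, n)  # angle, upper idx, lower idx
  for (u in 1:(n - 1)) {
    for (l in (u + 1):n) {
      ang <- abs(sup[u] - inf[l])
      if (ang > best[1] + 1e-12) best <- c(ang, u, l)
    }
  }
  upper <- level_range[best[2]]
  lower <- level_range[best[3]]
  # apex: level of max lateral deviation from the end-vertebra chord
  cen <- t(vapply(level_range, function(lv) landmark_coord(lm, lv, "centroid"),
                  numeric(3)))
  lat_axis <- if (plane == "frontal") 2L else 1L  # y for frontal, x for sagittal
  p0 <- cen[best[2], ]; p1 <- cen[best[3], ]
  dev <- vapply(seq_len(n), function(i) {
    t <- if (abs(p1[3] - p0[3]) > 1e-12) (cen[i, 3] - p0[3]) / (p1[3] - p0[3]) else 0
    chord <- p0 + t * (p1 - p0)
    cen[i, lat_axis] - chord[lat_axis]
  }, 0)
  inner <- seq(best[2], best[3])
  apex_i <- inner[which.max(abs(dev[inner]))]
  convex <- NA_character_
  if (plane == "frontal") {
    convex <- if (dev[apex_i] >= 0) "left" else "right"
  }
  list(angle = unname(best[1]), upper_end = unname(upper),
       lower_end = unname(lower), apex = unname(level_range[apex_i]),
       convex_side = convex)
}

#' Thoracic kyphosis angle
#'
#' Cobb-style sagittal angle between the bounding endplate lines over the
#' configured thoracic range (default T1-T12).
#'
#' @param lm a `landmark_set`.
#' @param levels level range, default `"T1"` through `"T12"`.
#' @return Angle in degrees.
#' @export
kyphosis <- function(lm, levels = paste0("T", 1:12)) {
  cobb_angle(lm, plane = "sagittal", level_range = levels)$angle
}

#' Lumbar lordosis angle
#'
#' Cobb-style sagittal angle over the lumbar range (default L1-L5; the
#' model has no sacrum).
#'
#' @inheritParams kyphosis
#' @param levels level range, default `"L1"` through `"L5"`.
#' @return Angle in degrees.
#' @export
lordosis <- function(lm, levels = paste0("L", 1:5)) {
  cobb_angle(lm, plane = "sagittal", level_range = levels)$angle
}

#' Frontal vertebral-body wedging angle
#'
#' Angle between the superior and inferior endplate lines of one vertebral
#' body in the frontal plane, signed positive when the wedge opens toward
#' the convexity of the curve (taller on the convex side).
#'
#' @param lm a `landmark_set`.
#' @param level level label.
#' @param convex_side `"left"`, `"right"`, or `NULL` to determine it from
#'   a frontal Cobb measurement over the whole set.
#' @return Signed angle in degrees.
#' @export
wedging_angle <- function(lm, level, convex_side = NULL) {
  for (id in c("sup_left", "sup_right", "inf_left", "inf_right")) {
    # degenerate geometry guard
    p <- landmark_coord(lm, level, id)
  }
  sl <- landmark_coord(lm, level, "sup_left")
  sr <- landmark_coord(lm, level, "sup_right")
  il <- landmark_coord(lm, level, "inf_left")
  ir <- landmark_coord(lm, level, "inf_right")
  if (sum((sl - sr)^2) < 1e-12 || sum((il - ir)^2) < 1e-12) {
    stop("degenerate endplate corners at level ", level)
  }
  if (is.null(convex_side)) {
    convex_side <- cobb_angle(lm, plane = "frontal")$convex_side
  }
  raw <- endplate_tilt(lm, level, "sup", "frontal") -
    endplate_tilt(lm, level, "inf", "frontal")
  # raw > 0 <=> taller on the patient-left side
  if (identical(convex_side, "right")) raw <- -raw
  raw
}

#' Apical axial rotation
#'
#' Transverse-plane angle between the vertebra's local left-right axis
#' (joining the midpoints of the left and right frontal corner pairs) and
#' the global +y (patient-left) axis.
#'
#' @param lm a `landmark_set`.
#' @param level level label.
#' @return Angle in degrees (signed; positive = left side rotated
#'   anteriorly).
#' @export
axial_rotation <- function(lm, level) {
  left <- (landmark_coord(lm, level, "sup_left") +
             landmark_coord(lm, level, "inf_left")) / 2
  right <- (landmark_coord(lm, level, "sup_right") +
              landmark_coord(lm, level, "inf_right")) / 2
  ax <- left - right
  if (sum(ax[1:2]^2) < 1e-12) stop("degenerate left-right axis at level ", level)
  rad2deg(atan2(ax[1], ax[2]))
}

#' Measure the full set of clinical indices
#'
#' Convenience wrapper producing thoracic and lumbar Cobb, kyphosis,
#' lordosis, apical axial rotation and wedging at the apex and the two
#' adjacent levels.
#'
#' @param lm a `landmark_set` (complete or covering the default ranges).
#' @param thoracic_range,lumbar_range level ranges for the frontal Cobb
#'   search (defaults T1-T12 and T12-L5).
#' @return Object of class `clinical_indices`: a list with fields
#'   `thoracic_cobb`, `lumbar_cobb`, `kyphosis`, `lordosis`,
#'   `axial_rotation`, `apex`, `convex_side`, and `wedging` (named vector:
#'   apex-1, apex, apex+1).
#' @export
measure_indices <- function(lm, thoracic_range = paste0("T", 1:12),
                            lumbar_range = c("T12", paste0("L", 1:5))) {
  th <- cobb_angle(lm, "frontal", thoracic_range)
  lu <- cobb_angle(lm, "frontal", lumbar_range)
  ky <- kyphosis(lm)
  lo <- lordosis(lm)
  apex <- th$apex
  ai <- level_index(apex)
  adj <- spine_levels()[pmax(1, pmin(17, c(ai - 1, ai, ai + 1)))]
  wedges <- vapply(adj, function(lv)
    wedging_angle(lm, lv, convex_side = th$convex_side), 0)
  names(wedges) <- c("apex_minus_1", "apex", "apex_plus_1")
  structure(list(
    thoracic_cobb = th$angle, lumbar_cobb = lu$angle,
    kyphosis = ky, lordosis = lo,
    axial_rotation = axial_rotation(lm, apex),
    apex = apex, convex_side = th$convex_side,
    wedging = wedges), class = "clinical_indices")
}

#' @export
print.clinical_indices <- function(x, ...) {
  cat(sprintf(paste0(
    "<clinical_indices>\n",
    "  thoracic Cobb: %.1f deg (apex %s, convex %s)\n",
    "  lumbar Cobb:   %.1f deg\n",
    "  kyphosis:      %.1f deg\n",
    "  lordosis:      %.1f deg\n",
    "  axial rot:     %.1f deg\n",
    "  wedging (apex-1, apex, apex+1): %.1f, %.1f, %.1f deg\n"),
    x$thoracic_cobb, x$apex, x$convex_side, x$lumbar_cobb, x$kyphosis,
    x$lordosis, x$axial_rotation, x$wedging[1], x$wedging[2], x$wedging[3]))
  invisible(x)
}

#' Compare measured indices against a reference
#'
#' Absolute per-index, per-timepoint errors with a clinical acceptability
#' threshold (default 8 degrees, the 95% confidence bound on manual
#' radiographic angle measurement).
#'
#' @param model_indices,reference_indices data frames with a `timepoint`
#'   column plus one numeric column per index (same columns in both).
#' @param threshold pass threshold in degrees, default 8.
#' @return List with `errors` (data frame of absolute differences), `pass`
#'   (logical data frame), and `summary` (per-index mean and sd formatted
#'   `"m +/- s"`).
#' @export
compare_indices <- function(model_indices, reference_indices, threshold = 8) {
  m <- as.data.frame(model_indices)
  r <- as.data.frame(reference_indices)
  if (!identical(sort(names(m)), sort(names(r)))) {
    stop("model and reference index tables have different columns")
  }
  if (!"timepoint" %in% names(m)) stop("index tables need a timepoint column")
  if (!isTRUE(all.equal(sort(m$timepoint), sort(r$timepoint)))) {
    stop("timepoint mismatch between model and reference")
  }
  m <- m[order(m$timepoint), ]
  r <- r[order(r$timepoint), ]
  idx_cols <- setdiff(names(m), "timepoint")
  err <- abs(m[idx_cols] - r[idx_cols])
  pass <- err < threshold
  summ <- vapply(idx_cols, function(cn) {
    sprintf("%.1f ± %.1f", mean(err[[cn]]), stats::sd(err[[cn]]))
  }, "")
  list(errors = cbind(timepoint = m$timepoint, err),
       pass = cbind(timepoint = m$timepoint, as.data.frame(pass)),
       summary = summ)
}
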