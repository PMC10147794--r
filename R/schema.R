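#' Vertebral level labels, T1 to L5
#'
#' Ordered cranial-to-caudal labels of the 17 thoracolumbar vertebral levels
#' covered by the model (12 thoracic + 5 lumbar; no sacrum).
#'
#' @return Character vector of length 17: `"T1" ... "T12", "L1" ... "L5"`.
#' @export
spine_levels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

#' Landmark identifiers per vertebra
#'
#' Nine named landmarks per vertebral body: the four frontal-plane body
#' corners, the four sagittal-plane body corners, and the body centroid.
#'
#' @return Character vector of length 9.
#' @export
landmark_ids <- function() {
  c("sup_left", "sup_right", "inf_left", "inf_right",
    "sup_ant", "sup_post", "inf_ant", "inf_post",
    "centroid")
}

#' The 13 vertebral growth regions
#'
#' Region identifiers used for growth-coefficient allocation: the four
#' vertebral-body quadrants (which receive stress modulation) plus nine
#' posterior-element regions (which do not).
#'
#' @return Character vector of length 13.
#' @export
region_ids <- function() {
  c("body_ant_left", "body_ant_right", "body_post_left", "body_post_right",
    "pedicle_left", "pedicle_right", "lamina_left", "lamina_right",
    "transverse_left", "transverse_right", "spinous",
    "facet_left", "facet_right")
}

#' Body-quadrant region identifiers
#'
#' The four vertebral-body quadrant regions whose vertical growth is
#' modulated by intervertebral-disc stress.
#'
#' @return Character vector of length 4.
#' @export
body_quadrants <- function() {
  c("body_ant_left", "body_ant_right", "body_post_left", "body_post_right")
}

#' Growth directions
#'
#' The three orthotropic growth directions in the vertebral local frame.
#'
#' @return Character vector `c("vertical", "lateral", "antero_posterior")`.
#' @export
growth_directions <- function() {
  c("vertical", "lateral", "antero_posterior")
}

# ordinal position of a level label in the cranial-to-caudal sequence
level_index <- function(level) {
  idx <- match(level, spine_levels())
  if (anyNA(idx)) {
    stop("unknown vertebral level(s): ",
         paste(unique(level[is.na(idx)]), collapse = ", "))
  }
  idx
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
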