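#' Default vertebral dimension table
#'
#' Level-interpolated pediatric-plausible vertebral body dimensions for a
#' roughly 10-12 year old: transverse width (y extent), antero-posterior
#' depth (x extent) and body height (z extent), plus the height of the
#' intervertebral disc below each level (mm). Values increase smoothly
#' from T1 to L5; the disc below L5 is outside the modeled column and is
#' recorded as 0.
#'
#' @param scale global scale factor applied to all dimensions (default 1).
#' @return Data frame with columns `level`, `width`, `depth`, `height`,
#'   `ivd_height` (17 rows, T1 to L5).
#' @export
default_dimension_table <- function(scale = 1) {
  lv <- spine_levels()
  t <- (seq_along(lv) - 1) / 16  # 0 at T1, 1 at L5
  data.frame(
    level = lv,
    width = scale * (26 + 16 * t),      # 26 -> 42 mm
    depth = scale * (16 + 15 * t),      # 16 -> 31 mm
    height = scale * (13 + 10 * t),     # 13 -> 23 mm
    ivd_height = scale * c(rep(NA, 0), (4 + 4 * t)[-17], 0))  # 4 -> ~8 mm
}

check_dimension_table <- function(dims) {
  need <- c("level", "width", "depth", "height", "ivd_height")
  if (!all(need %in% names(dims))) {
    stop("dimension table needs columns: ", paste(need, collapse = ", "))
  }
  miss <- setdiff(spine_levels(), dims$level)
  if (length(miss)) stop("dimension table missing level(s): ",
                         paste(miss, collapse = ", "))
  dims <- dims[match(spine_levels(), dims$level), ]
  num <- as.matrix(dims[c("width", "depth", "height")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("vertebral dimensions must be positive and finite")
  }
  if (any(dims$ivd_height[-17] <= 0) || any(!is.finite(dims$ivd_height[-17]))) {
    stop("ivd_height must be positive for T1..L4")
  }
  dims
}
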