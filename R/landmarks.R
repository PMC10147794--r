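#' @section Coordinate frame:
#' All three-dimensional coordinates use a right-handed global frame in
#' millimetres: +x anterior, +y patient-left, +z superior, origin at the
#' pelvis centre. The frontal (coronal) radiographic view is the (y, z)
#' plane and the lateral (sagittal) view the (x, z) plane.
#'
#' @name spinegrowth-frames
#' @keywords internal
NULL

#' Construct a 3D landmark set
#'
#' A `landmark_set` is a data frame with columns `level`, `id`, `x`, `y`,
#' `z` holding up to 153 named vertebral landmarks (9 per level, 17 levels)
#' in the global frame (mm). See [spine_levels()] and [landmark_ids()].
#'
#' @param df data frame with columns `level`, `id`, `x`, `y`, `z`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(df) {
  req <- c("level", "id", "x", "y", "z")
  if (!all(req %in% names(df))) {
    stop("landmark_set needs columns: ", paste(req, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  validate_keys(df$level, df$id)
  key <- paste(df$level, df$id)
  if (anyDuplicated(key)) {
    stop("duplicate landmark key(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  # canonical ordering: level cranial-to-caudal, then landmark id
  df <- df[order(level_index(df$level), match(df$id, landmark_ids())), ]
  rownames(df) <- NULL
  class(df) <- c("landmark_set", "data.frame")
  df
}

validate_keys <- function(level, id) {
  bad_lvl <- setdiff(unique(level), spine_levels())
  if (length(bad_lvl)) stop("unknown vertebral level(s): ", paste(bad_lvl, collapse = ", "))
  bad_id <- setdiff(unique(id), landmark_ids())
  if (length(bad_id)) stop("unknown landmark id(s): ", paste(bad_id, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points over %d levels\n",
              nrow(x), length(unique(x$level))))
  invisible(x)
}

#' Check completeness of a landmark set
#'
#' A complete patient has all 17 levels x 9 ids = 153 landmarks.
#'
#' @param lm a `landmark_set` or `biplanar_landmarks`.
#' @return Invisibly `TRUE` if complete; otherwise a character vector of
#'   missing `"level id"` keys (and `FALSE`-y length > 0).
#' @export
missing_landmarks <- function(lm) {
  if (inherits(lm, "biplanar_landmarks")) {
    have <- intersect(paste(lm$frontal$level, lm$frontal$id),
                      paste(lm$lateral$level, lm$lateral$id))
  } else {
    have <- paste(lm$level, lm$id)
  }
  full <- as.vector(outer(spine_levels(), landmark_ids(), paste))
  miss <- setdiff(full, have)
  if (!length(miss)) invisible(character(0)) else miss
}

#' Fetch one landmark coordinate
#' @param lm a `landmark_set`.
#' @param level,id landmark key.
#' @return Numeric length-3 vector (x, y, z).
#' @export
landmark_coord <- function(lm, level, id) {
  row <- lm[lm$level == level & lm$id == id, ]
  if (nrow(row) != 1) stop("landmark not found: ", level, " ", id)
  as.numeric(row[c("x", "y", "z")])
}

#' Construct biplanar (two-view) landmark observations
#'
#' Holds per-key frontal-view (y, z) and lateral-view (x, z) coordinates as
#' observed on calibrated orthographic biplanar radiographs.
#'
#' @param frontal data frame with columns `level`, `id`, `y`, `z` (mm).
#' @param lateral data frame with columns `level`, `id`, `x`, `z` (mm).
#' @return Object of class `biplanar_landmarks`.
#' @export
biplanar_landmarks <- function(frontal, lateral) {
  for (v in list(list(frontal, c("level", "id", "y", "z"), "frontal"),
                 list(lateral, c("level", "id", "x", "z"), "lateral"))) {
    if (!all(v[[2]] %in% names(v[[1]]))) {
      stop(v[[3]], " view needs columns: ", paste(v[[2]], collapse = ", "))
    }
    validate_keys(v[[1]]$level, v[[1]]$id)
    key <- paste(v[[1]]$level, v[[1]]$id)
    if (anyDuplicated(key)) {
      stop("duplicate key in ", v[[3]], " view: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  structure(list(frontal = as.data.frame(frontal)[c("level", "id", "y", "z")],
                 lateral = as.data.frame(lateral)[c("level", "id", "x", "z")]),
            class = "biplanar_landmarks")
}

#' @export
print.biplanar_landmarks <- function(x, ...) {
  cat(sprintf("<biplanar_landmarks> frontal: %d, lateral: %d points\n",
              nrow(x$frontal), nrow(x$lateral)))
  invisible(x)
}

#' Triangulate biplanar landmarks into 3D
#'
#' Orthographic two-view reconstruction: for each landmark key, x is taken
#' from the lateral view, y from the frontal view, and z as the arithmetic
#' mean of the two views' z readings. Disagreement in z beyond `z_tol`
#' raises a warning (the mean is still used).
#'
#' @param biplanar a `biplanar_landmarks` object.
#' @param z_tol tolerance (mm) on inter-view z disagreement. Default 10.
#' @return A `landmark_set`.
#' @export
triangulate <- function(biplanar, z_tol = 10) {
  stopifnot(inherits(biplanar, "biplanar_landmarks"))
  fr <- biplanar$frontal
  la <- biplanar$lateral
  key_f <- paste(fr$level, fr$id)
  key_l <- paste(la$level, la$id)
  only_f <- setdiff(key_f, key_l)
  only_l <- setdiff(key_l, key_f)
  if (length(only_f) || length(only_l)) {
    stop("landmark present in one view only: ",
         paste(c(only_f, only_l), collapse = "; "))
  }
  m <- match(key_f, key_l)
  dz <- abs(fr$z - la$z[m])
  if (any(dz > z_tol)) {
    bad <- key_f[dz > z_tol]
    warning("z disagreement beyond ", z_tol, " mm for: ",
            paste(bad, collapse = "; "), " (mean used)")
  }
  landmark_set(data.frame(level = fr$level, id = fr$id,
                          x = la$x[m], y = fr$y,
                          z = (fr$z + la$z[m]) / 2))
}

#' Project a 3D landmark set onto the two radiographic views
#'
#' Exact orthographic inverse of [triangulate()]: the frontal view records
#' (y, z) and the lateral view (x, z) of each point, so
#' `triangulate(project(lm))` recovers `lm` exactly.
#'
#' @param lm a `landmark_set`.
#' @return A `biplanar_landmarks` object.
#' @export
project <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  biplanar_landmarks(
    frontal = data.frame(level = lm$level, id = lm$id, y = lm$y, z = lm$z),
    lateral = data.frame(level = lm$level, id = lm$id, x = lm$x, z = lm$z))
}

#' Read landmarks from CSV
#'
#' The CSV dialect has a mandatory header `level,id,view,c1,c2,c3`. Rows
#' with `view` equal to `"frontal"` or `"lateral"` carry 2D observations
#' (`c1,c2` = frontal (y, z) or lateral (x, z)); rows with empty view (or
#' `view = "3d"`) carry 3D coordinates in `c1,c2,c3` = (x, y, z).
#' A file must be entirely 2D (both views) or entirely 3D.
#'
#' @param path CSV file path.
#' @return `biplanar_landmarks` or `landmark_set` depending on content.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(level = "character", id = "character"))
  need <- c("level", "id", "view", "c1", "c2")
  if (!all(need %in% names(df))) {
    stop("landmark CSV needs header columns: ", paste(need, collapse = ","),
         " (got: ", paste(names(df), collapse = ","), ")")
  }
  df$view[is.na(df$view)] <- ""
  bad <- which(!df$view %in% c("frontal", "lateral", "", "3d") |
                 is.na(df$c1) | is.na(df$c2))
  if (length(bad)) {
    stop("malformed landmark row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for header line
  }
  validate_keys(df$level, df$id)
  if (all(df$view %in% c("", "3d"))) {
    if (!"c3" %in% names(df) || anyNA(df$c3)) {
      stop("3D landmark rows need c3")
    }
    landmark_set(data.frame(level = df$level, id = df$id,
                            x = df$c1, y = df$c2, z = df$c3))
  } else if (all(df$view %in% c("frontal", "lateral"))) {
    fr <- df[df$view == "frontal", ]
    la <- df[df$view == "lateral", ]
    biplanar_landmarks(
      frontal = data.frame(level = fr$level, id = fr$id, y = fr$c1, z = fr$c2),
      lateral = data.frame(level = la$level, id = la$id, x = la$c1, z = la$c2))
  } else {
    stop("landmark CSV mixes 2D view rows and 3D rows")
  }
}

#' Write landmarks to CSV
#'
#' Lossless inverse of [read_landmarks()].
#'
#' @param obj a `landmark_set` or `biplanar_landmarks`.
#' @param path output CSV file path.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(obj, path) {
  if (inherits(obj, "landmark_set")) {
    out <- data.frame(level = obj$level, id = obj$id, view = "3d",
                      c1 = obj$x, c2 = obj$y, c3 = obj$z)
  } else if (inherits(obj, "biplanar_landmarks")) {
    fr <- obj$frontal
    la <- obj$lateral
    out <- rbind(
      data.frame(level = fr$level, id = fr$id, view = "frontal",
                 c1 = fr$y, c2 = fr$z, c3 = NA_real_),
      data.frame(level = la$level, id = la$id, view = "lateral",
                 c1 = la$x, c2 = la$z, c3 = NA_real_))
  } else {
    stop("unsupported object for write_landmarks")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# landmark_set -> n x 3 coordinate matrix (canonical row order)
landmark_matrix <- function(lm) {
  as.matrix(lm[, c("x", "y", "z")])
}
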