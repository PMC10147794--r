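#' Synthetic patient specification
#'
#' Parameters of the synthetic scoliotic spine generator: requested
#' frontal Cobb angles (thoracic, convex left; lumbar compensatory, convex
#' right), sagittal kyphosis and lordosis, curve ranges, vertebral
#' dimensions, landmark noise, and the accompanying clinical profile.
#' Defaults emulate a skeletally immature (Risser 0) 11-year-old girl with
#' a patient-left-convex 40 degree main thoracic curve, matching
#' the demographic make-up typical of progressive adolescent idiopathic
#' scoliosis cohorts.
#'
#' @param thoracic_cobb,lumbar_cobb,kyphosis,lordosis requested angles in
#'   degrees, each in \[0, 90\].
#' @param thoracic_range,lumbar_range level labels (upper end, lower end)
#'   bounding each frontal curve.
#' @param dims vertebral dimension table, see [default_dimension_table()].
#' @param noise_sd landmark Gaussian noise sd in mm (default 0).
#' @param seed RNG seed; mandatory when `noise_sd > 0`.
#' @param profile a [patient_profile()].
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(thoracic_cobb = 40, lumbar_cobb = 20,
                       kyphosis = 30, lordosis = 40,
                       thoracic_range = c("T5", "T11"),
                       lumbar_range = c("T12", "L4"),
                       dims = default_dimension_table(),
                       noise_sd = 0, seed = NULL,
                       profile = patient_profile(age = 11, sex = "F",
                                                 risser = 0, weight = 37,
                                                 cas = 46.3, calb = 13.7)) {
  angles <- c(thoracic_cobb, lumbar_cobb, kyphosis, lordosis)
  if (any(angles < 0 | angles > 90)) stop("requested angles must be in [0, 90]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd > 0 && is.null(seed)) stop("seed is mandatory when noise_sd > 0")
  structure(list(thoracic_cobb = thoracic_cobb, lumbar_cobb = lumbar_cobb,
                 kyphosis = kyphosis, lordosis = lordosis,
                 thoracic_range = thoracic_range, lumbar_range = lumbar_range,
                 dims = check_dimension_table(dims),
                 noise_sd = noise_sd, seed = seed, profile = profile),
            class = "synth_spec")
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

# Per-level frontal tilt profile (rad). The thoracic curve runs from
# +theta/2 at its upper end vertebra to -theta/2 at its lower end (convex
# toward patient-left, +y); the lumbar compensatory curve runs from
# -lambda/2 to +lambda/2 (convex right). A linear ramp-in above the
# thoracic curve and a halving decay below the lumbar one keep the
# adjacent-level tilt steps small (so discs stay well-shaped) without
# introducing tilts that exceed the end-vertebra tilts inside either
# measurement window - Cobb maximization therefore recovers the requested
# angles exactly.
frontal_profile <- function(thoracic_range, theta, lumbar_range, lambda,
                            ramp_in = 3) {
  u1 <- level_index(thoracic_range[1]); l1 <- level_index(thoracic_range[2])
  u2 <- level_index(lumbar_range[1]); l2 <- level_index(lumbar_range[2])
  if (l1 <= u1 || l2 <= u2) stop("curve range must run cranial to caudal")
  if (u2 <= l1) stop("lumbar curve must lie below the thoracic curve")
  phi <- numeric(17)
  r0 <- max(1, u1 - ramp_in)
  if (u1 > r0) phi[r0:u1] <- seq(0, theta / 2, length.out = u1 - r0 + 1)
  phi[u1:l1] <- seq(theta / 2, -theta / 2, length.out = l1 - u1 + 1)
  phi[l1:u2] <- seq(-theta / 2, -lambda / 2, length.out = u2 - l1 + 1)
  phi[u2:l2] <- seq(-lambda / 2, lambda / 2, length.out = l2 - u2 + 1)
  if (l2 < 17) {
    for (i in (l2 + 1):17) phi[i] <- phi[i - 1] / 2
  }
  phi
}

#' Generate a synthetic scoliotic patient
#'
#' Builds a T1-L5 spine whose per-level endplate orientations follow
#' piecewise-linear tilt profiles chosen analytically so that the standard
#' clinical measurements recover the requested angles exactly on
#' noise-free landmarks: the frontal profile spans +/- half the requested
#' Cobb angle over each curve range and the sagittal profile spans the
#' kyphosis (T1-T12) and lordosis (L1-L5) angles. Vertebral centroids are
#' chained bottom-up along the local tangent with spacing from the
#' dimension table; the frontal tilt is pre-compensated for projection
#' coupling with the sagittal tilt. Landmarks are the 8 body-corner
#' projections plus the centroid per level; optional Gaussian noise uses
#' the seeded generator.
#'
#' @param spec a [synth_spec()].
#' @return List with `landmarks` (a `landmark_set`), `biplanar` (exact
#'   projections, see [project()]), and `profile`.
#' @export
generate_patient <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  dims <- spec$dims
  phi <- frontal_profile(spec$thoracic_range, deg2rad(spec$thoracic_cobb),
                         spec$lumbar_range, deg2rad(spec$lumbar_cobb))
  # sagittal: kyphosis +k/2 (T1) -> -k/2 (T12); lordosis -l/2 (L1) -> +l/2 (L5)
  psi <- numeric(17)
  psi[1:12] <- deg2rad(spec$kyphosis) * (0.5 - (0:11) / 11)
  psi[13:17] <- deg2rad(spec$lordosis) * (-0.5 + (0:4) / 4)
  # frontal pre-compensation so the projected frontal tilt equals phi exactly
  phi_c <- atan(tan(phi) / cos(psi))
  rots <- lapply(1:17, function(i) rot_y(psi[i]) %*% rot_x(phi_c[i]))
  # chain centroids bottom-up (L5 at origin, z increasing to T1)
  cen <- matrix(0, 17, 3)
  for (i in 16:1) {
    s <- dims$height[i] / 2 + dims$ivd_height[i] + dims$height[i + 1] / 2
    step_rot <- rot_y((psi[i] + psi[i + 1]) / 2) %*%
      rot_x((phi_c[i] + phi_c[i + 1]) / 2)
    cen[i, ] <- cen[i + 1, ] + as.numeric(step_rot %*% c(0, 0, s))
  }
  cen <- sweep(cen, 2, cen[17, ])  # origin at L5 centroid (pelvis centre proxy)
  rows <- vector("list", 17 * 9)
  k <- 0
  for (i in 1:17) {
    hw <- dims$width[i] / 2; hd <- dims$depth[i] / 2; hh <- dims$height[i] / 2
    local <- rbind(
      sup_left = c(0, hw, hh), sup_right = c(0, -hw, hh),
      inf_left = c(0, hw, -hh), inf_right = c(0, -hw, -hh),
      sup_ant = c(hd, 0, hh), sup_post = c(-hd, 0, hh),
      inf_ant = c(hd, 0, -hh), inf_post = c(-hd, 0, -hh),
      centroid = c(0, 0, 0))
    glob <- t(rots[[i]] %*% t(local)) + matrix(cen[i, ], 9, 3, byrow = TRUE)
    for (j in 1:9) {
      k <- k + 1
      rows[[k]] <- data.frame(level = dims$level[i], id = rownames(local)[j],
                              x = glob[j, 1], y = glob[j, 2], z = glob[j, 3])
    }
  }
  lm_df <- do.call(rbind, rows)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    lm_df[c("x", "y", "z")] <- lm_df[c("x", "y", "z")] +
      stats::rnorm(3 * nrow(lm_df), sd = spec$noise_sd)
  }
  lm <- landmark_set(lm_df)
  list(landmarks = lm, biplanar = project(lm), profile = spec$profile)
}

#' Generate a cohort of synthetic patients on disk
#'
#' Writes one subdirectory per patient containing `landmarks.csv` (3D),
#' `biplanar.csv`, `profile.yaml` and a `manifest.json` describing the
#' generating parameters.
#'
#' @param specs named list of [synth_spec()] objects; names are patient
#'   ids (must be unique and non-empty).
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of per-patient directories.
#' @export
generate_cohort <- function(specs, dir) {
  if (!length(specs)) stop("empty spec list")
  ids <- names(specs)
  if (is.null(ids) || any(!nzchar(ids))) stop("specs must be a named list")
  if (anyDuplicated(ids)) stop("duplicate patient ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    pdir <- file.path(dir, ids[i])
    dir.create(pdir, showWarnings = FALSE)
    pat <- generate_patient(spec)
    write_landmarks(pat$landmarks, file.path(pdir, "landmarks.csv"))
    write_landmarks(pat$biplanar, file.path(pdir, "biplanar.csv"))
    prof <- pat$profile
    yaml::write_yaml(list(age = prof$age, sex = prof$sex,
                          risser = prof$risser, weight = prof$weight,
                          cas = prof$cas, calb = prof$calb,
                          sfr = round(prof$sfr, 2),
                          timepoints = prof$timepoints),
                     file.path(pdir, "profile.yaml"))
    manifest <- list(patient_id = ids[i],
                     thoracic_cobb = spec$thoracic_cobb,
                     lumbar_cobb = spec$lumbar_cobb,
                     kyphosis = spec$kyphosis, lordosis = spec$lordosis,
                     noise_sd = spec$noise_sd, seed = spec$seed)
    jsonlite::write_json(manifest, file.path(pdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out[i] <- pdir
  }
  invisible(out)
}

#' Read a patient profile from YAML
#'
#' @param path YAML file written by [generate_cohort()] (or hand-authored
#'   with the same fields).
#' @return A [patient_profile()].
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  patient_profile(age = y$age, sex = y$sex, risser = y$risser,
                  weight = y$weight, cas = y$cas, calb = y$calb,
                  timepoints = as.numeric(unlist(y$timepoints)))
}
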