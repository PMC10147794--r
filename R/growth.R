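#' Growth-law parameters
#'
#' Stress sensitivity decays linearly with skeletal maturity:
#' `beta(risser) = max(0, beta0 - risser * beta_slope)` (MPa^-1), so that
#' growth modulation vanishes at Risser 5 (skeletal maturity). The
#' baseline vertical body growth strain rate is `g0_vertical` per year at
#' Risser 0 declining linearly to zero at Risser 5; lateral and
#' antero-posterior baseline rates are set relative to the vertical one.
#'
#' @param beta0 stress sensitivity at Risser 0, default 0.4 MPa^-1.
#' @param beta_slope decrement per Risser grade, default 0.08.
#' @param g0_vertical baseline vertical growth strain per year at Risser
#'   0, default 0.04.
#' @param transverse_ratio lateral and antero-posterior baseline rates as
#'   a fraction of the vertical rate, default 0.3.
#' @param sex_factor named multipliers applied to baseline growth by sex.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(beta0 = 0.4, beta_slope = 0.08,
                          g0_vertical = 0.04, transverse_ratio = 0.3,
                          sex_factor = c(F = 1, M = 1)) {
  if (beta0 < 0) stop("beta0 must be >= 0")
  structure(list(beta0 = beta0, beta_slope = beta_slope,
                 g0_vertical = g0_vertical,
                 transverse_ratio = transverse_ratio,
                 sex_factor = sex_factor),
            class = "growth_params")
}

#' Stress sensitivity from the Risser sign
#'
#' `beta = max(0, beta0 - risser * slope)`; with the defaults, 0.4 MPa^-1
#' at Risser 0 and 0 at Risser 5.
#'
#' @param risser Risser sign in \[0, 5\] (fractional values allowed for
#'   interpolated maturity).
#' @param params a [growth_params()].
#' @return Stress sensitivity in MPa^-1.
#' @export
beta_from_risser <- function(risser, params = growth_params()) {
  if (any(risser < 0 | risser > 5)) stop("Risser sign must be in [0, 5]")
  pmax(0, params$beta0 - risser * params$beta_slope)
}

#' Stress-modulated growth (Hueter-Volkmann law)
#'
#' `G = G_m * (1 + beta * (sigma - sigma_m))`, floored at zero (no
#' resorption). `sigma` is tension-positive inside the law: extra
#' compression (`sigma < sigma_m`) inhibits growth, relative tension
#' stimulates it.
#'
#' @param g_m baseline growth under baseline stress (strain or mm).
#' @param beta stress sensitivity (MPa^-1).
#' @param sigma local stress (MPa, tension positive).
#' @param sigma_m baseline stress (MPa, tension positive).
#' @return Modulated growth, same units as `g_m`.
#' @export
modulated_growth <- function(g_m, beta, sigma, sigma_m) {
  pmax(0, g_m * (1 + beta * (sigma - sigma_m)))
}

#' Baseline growth-strain table
#'
#' Normative age/sex-based growth strain rates per (level, direction) in
#' strain per year at the given maturity. Uniform over levels by default
#' (published normative pediatric growth tables can be supplied instead
#' via the same columns).
#'
#' @param profile a [patient_profile()].
#' @param params a [growth_params()].
#' @param risser optional maturity override (e.g. interpolated mid-
#'   simulation); defaults to the profile's initial value.
#' @return Data frame `level`, `direction`, `rate` (51 rows).
#' @export
baseline_growth_table <- function(profile, params = growth_params(),
                                  risser = NULL) {
  if (is.null(risser)) risser <- profile$risser[1]
  maturity <- max(0, 1 - risser / 5)
  sf <- params$sex_factor[[profile$sex]]
  vert <- params$g0_vertical * maturity * sf
  data.frame(
    level = rep(spine_levels(), times = 3),
    direction = rep(growth_directions(), each = 17),
    rate = rep(c(vert, vert * params$transverse_ratio,
                 vert * params$transverse_ratio), each = 17))
}

#' Allocate the full set of growth coefficients
#'
#' Populates one eigenstrain-rate coefficient per (level, region,
#' direction): 17 x 13 x 3 = 663 entries, initialized from the baseline
#' growth table (regions inherit their level/direction rate).
#'
#' @param baseline data frame `level`, `direction`, `rate` (see
#'   [baseline_growth_table()]).
#' @param profile a [patient_profile()] (kept for provenance).
#' @return Object of class `growth_coefficients`: data frame `level`,
#'   `region`, `direction`, `alpha` (strain per year).
#' @export
allocate_coefficients <- function(baseline, profile = NULL) {
  need <- expand.grid(level = spine_levels(), direction = growth_directions(),
                      stringsAsFactors = FALSE)
  key <- paste(baseline$level, baseline$direction)
  m <- match(paste(need$level, need$direction), key)
  if (anyNA(m)) {
    miss <- need[is.na(m), ]
    stop("baseline growth table missing entries, e.g. ",
         miss$level[1], "/", miss$direction[1])
  }
  grid <- expand.grid(level = spine_levels(), region = region_ids(),
                      direction = growth_directions(),
                      stringsAsFactors = FALSE)
  grid$alpha <- baseline$rate[match(paste(grid$level, grid$direction), key)]
  stopifnot(nrow(grid) == 663)
  class(grid) <- c("growth_coefficients", "data.frame")
  grid
}

#' @export
print.growth_coefficients <- function(x, ...) {
  cat(sprintf("<growth_coefficients> %d entries, vertical body mean %.4f /y\n",
              nrow(x), mean(x$alpha[x$region %in% body_quadrants() &
                                      x$direction == "vertical"])))
  invisible(x)
}

#' Modulate body-quadrant vertical growth by IVD stress
#'
#' Scales only the (body quadrant, vertical) coefficients by the
#' Hueter-Volkmann bracket `1 + beta (sigma - sigma_m)` using the axial
#' stress of the matching quadrant of the disc below each vertebra (the
#' disc above for L5, which has no disc below). The per-level baseline
#' stress `sigma_m` is the mean of that disc's four quadrant stresses, so
#' a symmetric stress state leaves the coefficients unchanged. All other
#' entries (posterior regions, non-vertical directions) are untouched.
#'
#' @param coeffs a `growth_coefficients` object.
#' @param quadrant_stresses named list: per level label, a named numeric
#'   of tension-positive axial stresses `ant_left`, `ant_right`,
#'   `post_left`, `post_right` (MPa) for the disc below that level.
#'   Levels T1-L4; L5 reuses the L4 entry.
#' @param beta stress sensitivity (MPa^-1).
#' @return The updated `growth_coefficients`.
#' @export
modulate_quadrants <- function(coeffs, quadrant_stresses, beta) {
  quad_of <- c(body_ant_left = "ant_left", body_ant_right = "ant_right",
               body_post_left = "post_left", body_post_right = "post_right")
  for (lvl in spine_levels()) {
    src <- if (lvl == "L5") "L4" else lvl
    qs <- quadrant_stresses[[src]]
    if (is.null(qs)) stop("missing quadrant stresses for level ", src)
    if (!all(unname(quad_of) %in% names(qs))) {
      stop("quadrant stress vector for ", src, " lacks a quadrant")
    }
    sigma_m <- mean(qs[unname(quad_of)])
    for (b in names(quad_of)) {
      sel <- coeffs$level == lvl & coeffs$region == b &
        coeffs$direction == "vertical"
      coeffs$alpha[sel] <- modulated_growth(coeffs$alpha[sel], beta,
                                            qs[[quad_of[[b]]]], sigma_m)
    }
  }
  coeffs
}

# per-element global Voigt eigenstrain for one interval.
# vertical growth acts along the level's local spine axis, lateral along
# the local left-right axis, antero-posterior along the local
# anterior axis; only vertebral body hexes grow.
growth_eigenstrain <- function(model, coeffs, dt) {
  ne <- nrow(model$hexes)
  eig <- matrix(0, ne, 6)
  for (lvl in spine_levels()) {
    sel <- which(model$elem$structure == "vertebra" & model$elem$level == lvl)
    if (!length(sel)) next
    zl <- level_axis(model, lvl)
    xl <- c(1, 0, 0) - sum(c(1, 0, 0) * zl) * zl
    xl <- unit(xl)
    yl <- cross3(zl, xl)
    R <- cbind(xl, yl, zl)
    for (q in body_quadrants()) {
      a <- coeffs$alpha[coeffs$level == lvl & coeffs$region == q]
      names(a) <- coeffs$direction[coeffs$level == lvl & coeffs$region == q]
      eps_loc <- diag(c(a[["antero_posterior"]], a[["lateral"]],
                        a[["vertical"]])) * dt
      Eg <- R %*% eps_loc %*% t(R)
      v <- c(Eg[1, 1], Eg[2, 2], Eg[3, 3],
             2 * Eg[1, 2], 2 * Eg[2, 3], 2 * Eg[1, 3])
      eq <- sel[model$elem$region[sel] == q]
      eig[eq, ] <- matrix(v, length(eq), 6, byrow = TRUE)
    }
  }
  eig
}

#' Advance the model through one growth interval
#'
#' Staggered scheme: (1) two-pass gravity gives the standing stress state
#' at the current geometry; (2) body-quadrant vertical growth
#' coefficients are modulated by the matching IVD quadrant stresses at
#' the current stress sensitivity; (3) a single eigenstrain solve applies
#' the interval's growth strains; (4) the displaced nodes become the new
#' reference configuration and stresses are reset.
#'
#' @param model a `hex_mesh` with materials.
#' @param profile a [patient_profile()].
#' @param params a [growth_params()].
#' @param t_start interval start time (years from the initial timepoint).
#' @param dt interval length in years (default 0.5, the six-month
#'   follow-up spacing).
#' @param gravity_table see [default_gravity_table()].
#' @param beta override the stress sensitivity (default: from the
#'   interpolated Risser sign at `t_start`).
#' @return List with `model` (grown), `stress` (pre-growth standing
#'   stresses), `coeffs` (modulated coefficients used), `beta`.
#' @export
advance_interval <- function(model, profile, params = growth_params(),
                             t_start = 0, dt = 0.5,
                             gravity_table = default_gravity_table(),
                             beta = NULL) {
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) {
    return(list(model = model, stress = NULL, coeffs = NULL, beta = NULL))
  }
  risser_now <- risser_at(profile, t_start)
  if (is.null(beta)) beta <- beta_from_risser(risser_now, params)
  coeffs <- allocate_coefficients(
    baseline_growth_table(profile, params, risser = risser_now), profile)
  asm <- assemble_system(model)
  gv <- apply_gravity_two_pass(model, profile$weight, gravity_table, asm = asm)
  qs <- lapply(spine_levels()[1:16], function(lvl) {
    ivd_quadrant_stress_raw(model, gv$stress, lvl, asm)
  })
  names(qs) <- spine_levels()[1:16]
  coeffs <- modulate_quadrants(coeffs, qs, beta)
  eig <- growth_eigenstrain(model, coeffs, dt)
  sol <- resolve_tension_only(model, load_case(eigenstrain = eig), asm)
  model$nodes <- model$nodes + sol$u
  list(model = model, stress = gv$stress, coeffs = coeffs, beta = beta,
       quadrant_stresses = qs)
}

#' Simulate scoliotic growth over the documented follow-up
#'
#' Runs the full pipeline from a patient landmark set: template build,
#' kriging morph, material assignment, then stress-modulated growth
#' stepped over the profile's timepoints (subdivided into steps of at
#' most `dt_max` years). Clinical indices and apical IVD quadrant
#' stresses are recorded at every documented timepoint.
#'
#' @param landmarks a complete `landmark_set` at the initial timepoint.
#' @param profile a [patient_profile()].
#' @param params a [growth_params()].
#' @param cards material cards, default [default_material_cards()] at the
#'   profile's age.
#' @param template optional prebuilt template `hex_mesh`.
#' @param refinement template refinement if no template is supplied.
#' @param gravity_table see [default_gravity_table()].
#' @param dt_max maximum growth step in years, default 0.5.
#' @return Object of class `growth_trajectory`: list with `indices` (data
#'   frame per timepoint), `quadrant_stress` (data frame: timepoint,
#'   level, quadrant, stress_MPa, compression positive), `models` (list
#'   of `hex_mesh` per timepoint), `profile`, and `manifest`.
#' @export
simulate_growth <- function(landmarks, profile, params = growth_params(),
                            cards = default_material_cards(profile$age),
                            template = NULL, refinement = c(4, 4, 2),
                            gravity_table = default_gravity_table(),
                            dt_max = 0.5) {
  stopifnot(inherits(landmarks, "landmark_set"),
            inherits(profile, "patient_profile"))
  if (is.null(template)) template <- build_template(refinement = refinement)
  model <- morph_model(template, landmarks)
  model <- assign_materials(model, cards, profile)
  tp <- profile$timepoints
  if (tp[1] != 0) tp <- c(0, tp)
  convex <- cobb_angle(landmarks)$convex_side
  indices <- list()
  qstress <- list()
  models <- list()
  record <- function(t, model, stress_asm = NULL) {
    lm <- mesh_landmarks(model)
    ci <- measure_indices(lm)
    indices[[length(indices) + 1]] <<- data.frame(
      timepoint = t, thoracic_cobb = ci$thoracic_cobb,
      lumbar_cobb = ci$lumbar_cobb, kyphosis = ci$kyphosis,
      lordosis = ci$lordosis, axial_rotation = ci$axial_rotation,
      wedge_apex_minus_1 = ci$wedging[["apex_minus_1"]],
      wedge_apex = ci$wedging[["apex"]],
      wedge_apex_plus_1 = ci$wedging[["apex_plus_1"]],
      apex = ci$apex)
    # standing stresses at this timepoint, reported at the apical disc
    asm <- assemble_system(model)
    gv <- apply_gravity_two_pass(model, profile$weight, gravity_table,
                                 asm = asm)
    qs <- ivd_quadrant_stress(model, gv$stress, ci$apex, convex, asm)
    qstress[[length(qstress) + 1]] <<- data.frame(
      timepoint = t, level = ci$apex, quadrant = names(qs),
      stress_MPa = unname(qs))
    models[[as.character(t)]] <<- model
  }
  record(tp[1], model)
  for (k in seq_len(length(tp) - 1)) {
    span <- tp[k + 1] - tp[k]
    nstep <- max(1, ceiling(span / dt_max))
    dt <- span / nstep
    for (s in seq_len(nstep)) {
      t0 <- tp[k] + (s - 1) * dt
      step <- advance_interval(model, profile, params, t_start = t0, dt = dt,
                               gravity_table = gravity_table)
      model <- step$model
    }
    record(tp[k + 1], model)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("spinegrowth")),
    profile = unclass(profile)[c("age", "sex", "risser", "weight",
                                 "cas", "calb", "sfr")],
    params = unclass(params),
    config_hash = digest::digest(list(unclass(profile), unclass(params),
                                      gravity_table, dt_max)))
  structure(list(indices = do.call(rbind, indices),
                 quadrant_stress = do.call(rbind, qstress),
                 models = models, profile = profile, manifest = manifest),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat("<growth_trajectory>\n")
  print(x$indices[, c("timepoint", "thoracic_cobb", "lumbar_cobb",
                      "kyphosis", "lordosis", "wedge_apex")], digits = 3)
  invisible(x)
}
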