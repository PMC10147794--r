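#' Spine flexibility ratio (SFR)
#'
#' `SFR = (CAS - CALB) / CAS`, where CAS is the standing Cobb angle at the
#' final timepoint and CALB the Cobb angle during lateral bending into the
#' convexity. Higher values indicate a more flexible curve. Printed to two
#' decimals by convention.
#'
#' @param cas standing Cobb angle (deg), must be > 0.
#' @param calb lateral-bending Cobb angle (deg).
#' @param clamp clamp the result into \[0, 1\]? Default `FALSE` (a value
#'   outside the unit interval raises a warning instead).
#' @return Dimensionless ratio.
#' @export
compute_sfr <- function(cas, calb, clamp = FALSE) {
  if (any(cas <= 0)) stop("CAS must be positive")
  sfr <- (cas - calb) / cas
  out <- sfr < 0 | sfr > 1
  if (any(out)) {
    warning("SFR outside [0, 1]: ", paste(format(sfr[out]), collapse = ", "))
    if (clamp) sfr <- pmin(1, pmax(0, sfr))
  }
  sfr
}

#' Material card
#'
#' One anatomical structure's adult elastic modulus (MPa) or spring
#' stiffness (N/mm), Poisson ratio, and chronological-age scale factor.
#'
#' @param structure structure label (e.g. `"vertebra"`, `"ivd"`,
#'   `"ligament"`).
#' @param value adult modulus E (MPa) for solids or stiffness k (N/mm) for
#'   springs; > 0.
#' @param kind `"modulus"` or `"stiffness"`.
#' @param poisson Poisson ratio (solids only).
#' @param age_scale_factor dimensionless factor in (0, 1.2].
#' @return Object of class `material_card`.
#' @export
material_card <- function(structure, value, kind = c("modulus", "stiffness"),
                          poisson = NA_real_, age_scale_factor = 1) {
  kind <- match.arg(kind)
  if (value <= 0) stop("material value must be positive")
  if (age_scale_factor <= 0 || age_scale_factor > 1.2) {
    stop("age_scale_factor must be in (0, 1.2]")
  }
  structure(list(structure = structure, value = value, kind = kind,
                 poisson = poisson, age_scale_factor = age_scale_factor),
            class = "material_card")
}

#' Age scale factor by structure class
#'
#' Linear chronological-age schedules anchored so that a 16-year-old gets
#' 0.95 for bone/disc/rib, 0.97 for ligaments, and 0.94 for
#' costo-vertebral joint cartilage (published pediatric-to-adult scaling
#' is tabulated only sparsely; this linear interpolant passes through the
#' tabulated example and saturates at 1.0 in adulthood).
#'
#' @param age chronological age in years.
#' @param class one of `"bone"`, `"ligament"`, `"costovertebral"`.
#' @return Scale factor in (0, 1].
#' @export
default_age_scale <- function(age, class = c("bone", "ligament", "costovertebral")) {
  class <- match.arg(class)
  base <- switch(class, bone = 0.79, ligament = 0.81, costovertebral = 0.78)
  min(1, max(0.5, base + 0.01 * age))
}

#' Apply age scaling to a material card
#'
#' @param card a [material_card()].
#' @return The scaled modulus/stiffness (value x age_scale_factor).
#' @export
scale_by_age <- function(card) {
  stopifnot(inherits(card, "material_card"))
  card$value * card$age_scale_factor
}

#' Flexibility-scaled IVD elastic modulus
#'
#' `E_scaled = E_baseline * (1 - C x SFR)`: stiffer discs for rigid curves
#' (low SFR), softer for flexible ones. The modulation constant C defaults
#' to 0.3.
#'
#' @param e_baseline baseline (age-scaled) IVD modulus, MPa, > 0.
#' @param sfr spine flexibility ratio, see [compute_sfr()].
#' @param c modulation constant, default 0.3; `c * sfr` must be < 1.
#' @return Scaled modulus in MPa.
#' @export
scale_ivd_modulus <- function(e_baseline, sfr, c = 0.3) {
  if (e_baseline <= 0) stop("e_baseline must be positive")
  if (c * sfr >= 1) stop("c * sfr >= 1 gives a nonphysical (<= 0) modulus")
  e_baseline * (1 - c * sfr)
}

#' Default material cards
#'
#' Adult values with an age scale factor per structure class; ligament and
#' posterior spring stiffnesses are per-spring lumped defaults.
#'
#' @param age chronological age in years (drives [default_age_scale()]).
#' @return Named list of [material_card()] objects covering the template's
#'   structure labels: `vertebra`, `ivd`, `ligament`, `posterior`,
#'   `costovertebral`.
#' @export
default_material_cards <- function(age = 11) {
  bone_f <- default_age_scale(age, "bone")
  lig_f <- default_age_scale(age, "ligament")
  cv_f <- default_age_scale(age, "costovertebral")
  list(
    vertebra = material_card("vertebra", 350, "modulus", poisson = 0.3,
                             age_scale_factor = bone_f),
    ivd = material_card("ivd", 20, "modulus", poisson = 0.45,
                        age_scale_factor = bone_f),
    ligament = material_card("ligament", 20, "stiffness",
                             age_scale_factor = lig_f),
    posterior = material_card("posterior", 100, "stiffness",
                              age_scale_factor = bone_f),
    costovertebral = material_card("costovertebral", 48.9, "stiffness",
                                   age_scale_factor = cv_f))
}

#' Patient profile
#'
#' Demographics, skeletal maturity, weight, spine flexibility and
#' follow-up timepoints for one patient.
#'
#' @param age initial chronological age (years).
#' @param sex `"F"` or `"M"`.
#' @param risser Risser sign 0-5 at the initial timepoint, or a numeric
#'   vector of documented values, one per timepoint (non-decreasing).
#' @param weight body weight in kg.
#' @param cas standing Cobb angle at the final timepoint (deg).
#' @param calb Cobb angle during lateral bending into convexity (deg).
#' @param timepoints strictly increasing numeric vector of follow-up times
#'   in years from the initial timepoint (default 6-month intervals over
#'   three years).
#' @param c_sfr IVD flexibility modulation constant, default 0.3.
#' @return Object of class `patient_profile` with a precomputed `sfr`.
#' @export
patient_profile <- function(age, sex = c("F", "M"), risser = 0, weight = 40,
                            cas = 40, calb = 20,
                            timepoints = seq(0, 3, by = 0.5), c_sfr = 0.3) {
  sex <- match.arg(sex)
  if (any(risser < 0 | risser > 5)) stop("Risser sign must be in [0, 5]")
  if (is.unsorted(risser)) stop("documented Risser values must be non-decreasing")
  if (length(timepoints) < 1 || is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (!length(risser) %in% c(1L, length(timepoints))) {
    stop("risser must have length 1 or one value per timepoint")
  }
  structure(list(age = age, sex = sex, risser = risser, weight = weight,
                 cas = cas, calb = calb, sfr = compute_sfr(cas, calb),
                 timepoints = timepoints, c_sfr = c_sfr),
            class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf(
    "<patient_profile> age %.1f y, sex %s, Risser %s, weight %.1f kg, SFR %.2f\n",
    x$age, x$sex, paste(x$risser, collapse = "/"), x$weight, x$sfr))
  invisible(x)
}

# documented Risser linearly interpolated at time t (years from ITP);
# held constant when only one value is documented
risser_at <- function(profile, t) {
  r <- profile$risser
  if (length(r) == 1L) return(r)
  stats::approx(profile$timepoints, r, xout = t, rule = 2)$y
}

#' Assign patient-specific materials to a mesh model
#'
#' Every hex element receives an age-scaled elastic modulus and Poisson
#' ratio by structure label; IVD elements are additionally
#' flexibility-scaled via [scale_ivd_modulus()]. Spring stiffnesses are
#' age-scaled by their label's card.
#'
#' @param model a `hex_mesh` (see [build_template()]).
#' @param cards named list of [material_card()]s covering every structure
#'   and spring label in the model.
#' @param profile a [patient_profile()] (supplies SFR and the modulation
#'   constant C); `NULL` applies age scaling only.
#' @return The model with per-element `E`, `nu` and scaled spring
#'   stiffnesses filled in, plus an `material_log` attribute.
#' @export
assign_materials <- function(model, cards = default_material_cards(),
                             profile = NULL) {
  stopifnot(inherits(model, "hex_mesh"))
  structures <- unique(model$elem$structure)
  missing_cards <- setdiff(structures, names(cards))
  if (length(missing_cards)) {
    stop("no material card for structure(s): ",
         paste(missing_cards, collapse = ", "))
  }
  E <- numeric(nrow(model$elem))
  nu <- numeric(nrow(model$elem))
  log <- list()
  for (s in structures) {
    card <- cards[[s]]
    if (card$kind != "modulus") stop("hex structure ", s, " needs a modulus card")
    e_scaled <- scale_by_age(card)
    if (s == "ivd" && !is.null(profile)) {
      e_scaled <- scale_ivd_modulus(e_scaled, profile$sfr, profile$c_sfr)
    }
    sel <- model$elem$structure == s
    E[sel] <- e_scaled
    nu[sel] <- card$poisson
    log[[s]] <- e_scaled
  }
  model$elem$E <- E
  model$elem$nu <- nu
  if (nrow(model$springs)) {
    slabs <- unique(model$springs$label)
    miss <- setdiff(slabs, names(cards))
    if (length(miss)) stop("no material card for spring label(s): ",
                           paste(miss, collapse = ", "))
    base <- model$springs$stiffness0
    if (is.null(base)) base <- model$springs$stiffness
    for (s in slabs) {
      card <- cards[[s]]
      if (card$kind != "stiffness") stop("spring label ", s, " needs a stiffness card")
      sel <- model$springs$label == s
      model$springs$stiffness[sel] <- base[sel] * card$age_scale_factor
      log[[paste0("spring_", s)]] <- card$age_scale_factor
    }
    model$springs$stiffness0 <- base
  }
  attr(model, "material_log") <- log
  model
}
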