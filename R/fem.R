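#' Small-strain linear-elastic FE solver
#'
#' Trilinear 8-node hexahedra with 2x2x2 Gauss integration, isotropic
#' Hooke's law per element, springs (axial or isotropic 3-dof links,
#' optionally tension-only), fixed-displacement constraints, nodal forces
#' and per-element anisotropic eigenstrain ("thermal growth") loading.
#' Voigt order is (xx, yy, zz, xy, yz, zx) with engineering shear.
#'
#' @name fem
NULL

# natural coordinates of the 8 corners (VTK ordering)
HEX_XI <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))

# shape-function derivative matrix dN (8 x 3) at natural point xi
hex_dN <- function(xi) {
  t(vapply(1:8, function(a) {
    s <- HEX_XI[a, ]
    c(s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]),
      s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]),
      s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2])) / 8
  }, numeric(3)))
}

GAUSS_PTS <- as.matrix(expand.grid(x = c(-1, 1) / sqrt(3),
                                   y = c(-1, 1) / sqrt(3),
                                   z = c(-1, 1) / sqrt(3)))
GAUSS_DN <- lapply(seq_len(8), function(g) hex_dN(GAUSS_PTS[g, ]))
CENTER_DN <- hex_dN(c(0, 0, 0))

# isotropic elasticity matrix, Voigt (xx,yy,zz,xy,yz,zx), engineering shear
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 24) from dN in global coords (8 x 3)
b_matrix <- function(dNg) {
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- dNg[, 1]
  B[2, ix + 1] <- dNg[, 2]
  B[3, ix + 2] <- dNg[, 3]
  B[4, ix] <- dNg[, 2]; B[4, ix + 1] <- dNg[, 1]
  B[5, ix + 1] <- dNg[, 3]; B[5, ix + 2] <- dNg[, 2]
  B[6, ix] <- dNg[, 3]; B[6, ix + 2] <- dNg[, 1]
  B
}

# per-element integration cache: B at each Gauss point, weights, volume
element_cache <- function(coords) {
  Bs <- vector("list", 8)
  w <- numeric(8)
  for (g in 1:8) {
    J <- t(GAUSS_DN[[g]]) %*% coords      # 3 x 3
    dJ <- det(J)
    if (dJ <= 0) stop("non-positive Jacobian during assembly")
    dNg <- GAUSS_DN[[g]] %*% solve(t(J))  # dN wrt global coords
    Bs[[g]] <- b_matrix(dNg)
    w[g] <- dJ
  }
  Jc <- t(CENTER_DN) %*% coords
  Bc <- b_matrix(CENTER_DN %*% solve(t(Jc)))
  list(B = Bs, w = w, Bc = Bc, vol = sum(w))
}

#' Assemble the hex stiffness and integration cache for a model
#'
#' Elements must carry `E` and `nu` (see [assign_materials()]). The
#' returned object is reused across solves at a fixed geometry.
#'
#' @param model a `hex_mesh` with materials assigned.
#' @return Assembly object (opaque list) for [solve_static()].
#' @export
assemble_system <- function(model) {
  stopifnot(inherits(model, "hex_mesh"))
  if (is.null(model$elem$E)) stop("assign_materials() must run before assembly")
  ne <- nrow(model$hexes)
  nn <- nrow(model$nodes)
  caches <- vector("list", ne)
  Ds <- vector("list", ne)
  tl <- vector("list", ne)
  for (e in seq_len(ne)) {
    conn <- model$hexes[e, ]
    cache <- element_cache(model$nodes[conn, , drop = FALSE])
    D <- elastic_D(model$elem$E[e], model$elem$nu[e])
    ke <- matrix(0, 24, 24)
    for (g in 1:8) {
      ke <- ke + crossprod(cache$B[[g]], D %*% cache$B[[g]]) * cache$w[g]
    }
    dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
    tl[[e]] <- list(i = rep(dofs, times = 24), j = rep(dofs, each = 24),
                    x = as.vector(ke))
    caches[[e]] <- cache
    Ds[[e]] <- D
  }
  K <- Matrix::sparseMatrix(
    i = unlist(lapply(tl, `[[`, "i")),
    j = unlist(lapply(tl, `[[`, "j")),
    x = unlist(lapply(tl, `[[`, "x")),
    dims = c(3 * nn, 3 * nn))
  list(K = K, caches = caches, D = Ds, nn = nn, ne = ne,
       nodes = model$nodes)
}

# spring stiffness triplets for the given (sub)set of springs, directions
# frozen at the assembly geometry
spring_triplets <- function(springs, nodes) {
  if (!nrow(springs)) {
    return(list(i = integer(0), j = integer(0), x = numeric(0)))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(nrow(springs))) {
    a <- springs$node_a[s]; b <- springs$node_b[s]
    k <- springs$stiffness[s]
    if (springs$isotropic[s]) {
      Kb <- diag(3) * k
    } else {
      d <- nodes[b, ] - nodes[a, ]
      len <- sqrt(sum(d^2))
      if (len < 1e-9) stop("zero-length spring ", s)
      n <- d / len
      Kb <- k * outer(n, n)
    }
    da <- 3 * a - 2:0; db <- 3 * b - 2:0
    dofs <- c(da, db)
    Ks <- rbind(cbind(Kb, -Kb), cbind(-Kb, Kb))
    ii <- c(ii, rep(dofs, times = 6)); jj <- c(jj, rep(dofs, each = 6))
    xx <- c(xx, as.vector(Ks))
  }
  list(i = ii, j = jj, x = xx)
}

# spring axial elongation (projected on the frozen axis) per spring
spring_elongation <- function(springs, nodes, u) {
  vapply(seq_len(nrow(springs)), function(s) {
    a <- springs$node_a[s]; b <- springs$node_b[s]
    d <- nodes[b, ] - nodes[a, ]
    n <- d / sqrt(sum(d^2))
    sum(n * (u[b, ] - u[a, ]))
  }, 0)
}

#' Define a load case
#'
#' @param forces n x 3 matrix of nodal forces (N), or `NULL`.
#' @param eigenstrain e x 6 matrix of per-hex eigenstrain in global Voigt
#'   components (engineering shear), or `NULL`. Magnitudes above 0.2
#'   violate the small-strain assumption and raise an error.
#' @return Object of class `load_case`.
#' @export
load_case <- function(forces = NULL, eigenstrain = NULL) {
  if (!is.null(forces) && any(!is.finite(forces))) stop("forces must be finite")
  if (!is.null(eigenstrain)) {
    if (any(!is.finite(eigenstrain))) stop("eigenstrain must be finite")
    if (max(abs(eigenstrain)) >= 0.2) {
      stop("eigenstrain exceeds the small-strain bound (|eps| < 0.2); ",
           "use a smaller growth step")
    }
  }
  structure(list(forces = forces, eigenstrain = eigenstrain),
            class = "load_case")
}

#' Solve a static load case
#'
#' Direct sparse solve of `K u = f` with fixed-displacement constraints
#' eliminated. Stresses are recovered at element centers via
#' `sigma = D (B u - eps0)`.
#'
#' @param model a `hex_mesh` with materials.
#' @param loadcase a [load_case()].
#' @param asm assembly from [assemble_system()] (recomputed if `NULL`).
#' @param active_springs logical vector selecting the springs included in
#'   the stiffness (default all). Tension-only logic lives in
#'   [resolve_tension_only()].
#' @return List with `u` (n x 3 displacements, mm), `stress` (e x 6 Voigt,
#'   MPa), `reactions` (n x 3), `residual` (relative equilibrium
#'   residual on free dofs).
#' @export
solve_static <- function(model, loadcase, asm = NULL, active_springs = NULL) {
  stopifnot(inherits(model, "hex_mesh"), inherits(loadcase, "load_case"))
  if (is.null(asm)) asm <- assemble_system(model)
  nn <- asm$nn
  if (is.null(active_springs)) active_springs <- rep(TRUE, nrow(model$springs))
  st <- spring_triplets(model$springs[active_springs, , drop = FALSE],
                        asm$nodes)
  K <- asm$K
  if (length(st$x)) {
    K <- K + Matrix::sparseMatrix(i = st$i, j = st$j, x = st$x,
                                  dims = dim(asm$K))
  }
  f <- numeric(3 * nn)
  if (!is.null(loadcase$forces)) {
    f <- f + as.vector(t(loadcase$forces))
  }
  eig <- loadcase$eigenstrain
  if (!is.null(eig)) {
    for (e in seq_len(asm$ne)) {
      eps <- eig[e, ]
      if (all(eps == 0)) next
      cache <- asm$caches[[e]]
      Deps <- asm$D[[e]] %*% eps
      fe <- numeric(24)
      for (g in 1:8) fe <- fe + crossprod(cache$B[[g]], Deps) * cache$w[g]
      conn <- model$hexes[e, ]
      dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
      f[dofs] <- f[dofs] + fe
    }
  }
  fixed <- as.vector(t(model$constraints))
  free <- which(!fixed)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  # a properly constrained elastic system is SPD; a failed Cholesky means
  # unconstrained rigid-body modes (or a defective model)
  ch <- tryCatch(
    suppressWarnings(Matrix::Cholesky(Kff, perm = TRUE, LDL = FALSE)),
    error = function(err) {
      stop("singular system (unconstrained rigid-body modes?): ",
           conditionMessage(err))
    })
  uf <- as.numeric(Matrix::solve(ch, f[free], system = "A"))
  u <- numeric(3 * nn)
  u[free] <- uf
  # equilibrium residual on free dofs
  res <- as.numeric(K %*% u - f)
  denom <- max(sqrt(sum(f[free]^2)), 1e-30)
  residual <- sqrt(sum(res[free]^2)) / denom
  reactions <- matrix(res, nn, 3, byrow = TRUE)  # nonzero only at fixed dofs
  stress <- matrix(0, asm$ne, 6)
  for (e in seq_len(asm$ne)) {
    conn <- model$hexes[e, ]
    dofs <- as.vector(t(cbind(3 * conn - 2, 3 * conn - 1, 3 * conn)))
    eps_tot <- asm$caches[[e]]$Bc %*% u[dofs]
    if (!is.null(eig)) eps_tot <- eps_tot - eig[e, ]
    stress[e, ] <- as.numeric(asm$D[[e]] %*% eps_tot)
  }
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  list(u = matrix(u, nn, 3, byrow = TRUE), stress = stress,
       reactions = reactions, residual = residual)
}

#' Resolve tension-only springs by fixed-point iteration
#'
#' Starts with all springs active, deactivates tension-only springs found
#' in compression (negative axial elongation), and re-solves until the
#' active set is stable. Oscillating active sets abort after `max_iter`
#' with the last two sets reported.
#'
#' @inheritParams solve_static
#' @param max_iter iteration cap, default 20.
#' @return As [solve_static()], plus `active` (logical per spring) and
#'   `iterations`.
#' @export
resolve_tension_only <- function(model, loadcase, asm = NULL, max_iter = 20) {
  if (is.null(asm)) asm <- assemble_system(model)
  ns <- nrow(model$springs)
  active <- rep(TRUE, ns)
  seen <- list()
  for (it in seq_len(max_iter)) {
    sol <- solve_static(model, loadcase, asm, active_springs = active)
    if (!ns) return(c(sol, list(active = active, iterations = it)))
    elong <- spring_elongation(model$springs, asm$nodes, sol$u)
    new_active <- !(model$springs$tension_only & elong < -1e-12)
    if (all(new_active == active)) {
      return(c(sol, list(active = active, iterations = it)))
    }
    seen[[length(seen) + 1]] <- active
    active <- new_active
  }
  stop("tension-only iteration did not converge after ", max_iter,
       " iterations; last active counts: ",
       sum(seen[[length(seen)]]), " -> ", sum(active))
}

#' Default per-level bodyweight fraction table
#'
#' Cumulative fraction of bodyweight carried by the column grows linearly
#' from 0.14 above T1 to 0.55 at L5; the table stores the per-level
#' increments applied at each vertebral centroid (T1 carries the initial
#' 0.14 head/arms share).
#'
#' @return Data frame `level`, `fraction` (17 rows, increments summing to
#'   0.55).
#' @export
default_gravity_table <- function() {
  fr <- c(0.14, rep((0.55 - 0.14) / 16, 16))
  data.frame(level = spine_levels(), fraction = fr)
}

# nodal gravity force matrix (z direction), sign = -1 for gravity
gravity_forces <- function(model, weight, table, sign = -1) {
  g <- 9.81
  f <- matrix(0, nrow(model$nodes), 3)
  for (i in seq_len(nrow(table))) {
    lvl <- table$level[i]
    els <- which(model$elem$structure == "vertebra" & model$elem$level == lvl)
    if (!length(els)) stop("gravity table level without vertebra elements: ", lvl)
    nds <- unique(as.vector(model$hexes[els, ]))
    f[nds, 3] <- f[nds, 3] + sign * table$fraction[i] * weight * g / length(nds)
  }
  f
}

#' Two-pass anti-gravity loading protocol
#'
#' Pass 1 applies the per-level bodyweight forces upward from the imaged
#' geometry and takes the displaced configuration as the unloaded
#' geometry, discarding all stresses. Pass 2 applies the same magnitudes
#' downward. Under linear kinematics (stiffness frozen at the imaged
#' geometry) the final geometry equals the imaged one and the pass-2
#' stress state is the physiological standing stress at the imaged shape.
#' Tension-only springs are re-resolved in each pass, which can leave a
#' small final-geometry deviation; an RMS deviation above `rms_tol` (mm)
#' raises a warning.
#'
#' @param model a `hex_mesh` with materials, at the imaged geometry.
#' @param weight patient body weight (kg).
#' @param table gravity table, see [default_gravity_table()].
#' @param asm optional precomputed [assemble_system()] result.
#' @param rms_tol warning threshold on the final-vs-imaged RMS node
#'   deviation (mm), default 2.
#' @return List with `stress` (pass-2 element stresses, MPa, at the imaged
#'   geometry), `unloaded_nodes`, `rms_deviation`, and the pass-2
#'   solution `sol`.
#' @export
apply_gravity_two_pass <- function(model, weight, table = default_gravity_table(),
                                   asm = NULL, rms_tol = 2) {
  stopifnot(inherits(model, "hex_mesh"))
  if (is.null(asm)) asm <- assemble_system(model)
  f_up <- gravity_forces(model, weight, table, sign = +1)
  sol_up <- resolve_tension_only(model, load_case(forces = f_up), asm)
  unloaded <- model$nodes + sol_up$u
  sol_dn <- resolve_tension_only(model, load_case(forces = -f_up), asm)
  final <- unloaded + sol_dn$u
  rms <- sqrt(mean((final - model$nodes)^2))
  if (rms > rms_tol) {
    warning(sprintf("two-pass final geometry deviates from imaged by %.2f mm RMS", rms))
  }
  list(stress = sol_dn$stress, unloaded_nodes = unloaded,
       rms_deviation = rms, sol = sol_dn)
}

# element volumes (mm^3)
element_volumes <- function(model, asm = NULL) {
  if (!is.null(asm)) {
    return(vapply(asm$caches, `[[`, 0, "vol"))
  }
  vapply(seq_len(nrow(model$hexes)), function(e) {
    element_cache(model$nodes[model$hexes[e, ], , drop = FALSE])$vol
  }, 0)
}

# unit axis of the disc below `level` (from the lower body's superior
# endplate centroid to the upper body's inferior endplate centroid)
disc_axis <- function(model, level) {
  i <- level_index(level)
  if (i >= 17) stop("no IVD below ", level)
  lower <- spine_levels()[i + 1]
  top <- colMeans(model$nodes[model$inf_face[[level]], , drop = FALSE])
  bot <- colMeans(model$nodes[model$sup_face[[lower]], , drop = FALSE])
  unit(top - bot)
}

# unit local spine axis of a vertebral body level
level_axis <- function(model, level) {
  sup <- colMeans(model$nodes[model$sup_face[[level]], , drop = FALSE])
  inf <- colMeans(model$nodes[model$inf_face[[level]], , drop = FALSE])
  unit(sup - inf)
}

# tension-positive axial stress per IVD quadrant of the disc below `level`
# (volume-weighted over quadrant elements)
ivd_quadrant_stress_raw <- function(model, stress, level, asm = NULL) {
  i <- level_index(level)
  if (i >= 17) stop("no IVD below level ", level)
  sel <- which(model$elem$structure == "ivd" & model$elem$level == level)
  if (!length(sel)) stop("no IVD elements at level ", level)
  n <- disc_axis(model, level)
  vol <- element_volumes(model, asm)
  axial <- vapply(sel, function(e) {
    s <- stress[e, ]
    S <- matrix(c(s[1], s[4], s[6],
                  s[4], s[2], s[5],
                  s[6], s[5], s[3]), 3, 3)
    as.numeric(t(n) %*% S %*% n)
  }, 0)
  out <- vapply(c("ant_left", "ant_right", "post_left", "post_right"),
                function(q) {
                  k <- model$elem$region[sel] == q
                  if (!any(k)) stop("missing IVD quadrant ", q, " at ", level)
                  sum(axial[k] * vol[sel][k]) / sum(vol[sel][k])
                }, 0)
  out
}

#' IVD quadrant principal-axis stresses (reporting convention)
#'
#' Volume-weighted axial stress (along the local disc axis) in the four
#' quadrants of the disc below `level`, mapped from left/right to
#' convex/concave via the curve laterality and sign-flipped so that
#' compression is positive.
#'
#' @param model a `hex_mesh`.
#' @param stress e x 6 stress matrix from a solve.
#' @param level vertebral level whose inferior disc is queried (T1-L4).
#' @param convex_side `"left"` or `"right"` (from [cobb_angle()]).
#' @param asm optional assembly (reuses cached element volumes).
#' @return Named numeric: `ant_convex`, `ant_concave`, `post_convex`,
#'   `post_concave` (MPa, compression positive).
#' @export
ivd_quadrant_stress <- function(model, stress, level, convex_side = "left",
                                asm = NULL) {
  raw <- ivd_quadrant_stress_raw(model, stress, level, asm)
  # raw is tension-positive in left/right naming
  pick <- function(ap, side) -raw[[paste0(ap, "_", side)]]
  conv <- convex_side
  conc <- if (conv == "left") "right" else "left"
  c(ant_convex = pick("ant", conv), ant_concave = pick("ant", conc),
    post_convex = pick("post", conv), post_concave = pick("post", conc))
}
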