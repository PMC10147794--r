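#' Hexahedral spine mesh model
#'
#' A `hex_mesh` bundles the geometry and discrete structure of the reduced
#' parametric T1-L5 osteo-ligamentous model:
#' \itemize{
#'   \item `nodes`: n x 3 coordinate matrix (mm, global frame);
#'   \item `hexes`: e x 8 integer matrix of node indices in standard
#'     right-handed hexahedron corner ordering (bottom face
#'     counter-clockwise, then top face);
#'   \item `elem`: per-hex data frame with `structure` (`"vertebra"` /
#'     `"ivd"`), `level`, `region` (body quadrant or IVD quadrant), and,
#'     after [assign_materials()], `E` (MPa) and `nu`;
#'   \item `springs`: data frame `node_a`, `node_b`, `stiffness` (N/mm),
#'     `tension_only`, `isotropic`, `label`;
#'   \item `constraints`: n x 3 logical matrix of fixed displacement
#'     components;
#'   \item `corner_nodes`: map from (level, landmark id) to node index,
#'     giving the mesh-borne landmarks used for morphing and measurement;
#'   \item `sup_face`, `inf_face`: per-level endplate node index sets.
#' }
#'
#' @name hex_mesh
NULL

new_hex_mesh <- function(nodes, hexes, elem, springs, constraints,
                         corner_nodes, sup_face, inf_face, meta = list()) {
  dimnames(nodes) <- NULL
  structure(list(nodes = nodes, hexes = hexes, elem = elem,
                 springs = springs, constraints = constraints,
                 corner_nodes = corner_nodes,
                 sup_face = sup_face, inf_face = inf_face, meta = meta),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hexes (%d vertebra / %d ivd), %d springs\n",
              nrow(x$nodes), nrow(x$hexes),
              sum(x$elem$structure == "vertebra"),
              sum(x$elem$structure == "ivd"), nrow(x$springs)))
  invisible(x)
}

# structured grid of a box: returns nodes and the linear index function
box_grid <- function(x0, x1, y0, y1, z0, z1, nx, ny, nz) {
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  zs <- seq(z0, z1, length.out = nz + 1)
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  idx <- function(i, j, k) i + (nx + 1) * (j - 1) + (nx + 1) * (ny + 1) * (k - 1)
  list(nodes = as.matrix(g), idx = idx, nx = nx, ny = ny, nz = nz)
}

# hex connectivity of a structured grid (local indices, VTK corner order)
box_hexes <- function(g) {
  out <- matrix(0L, g$nx * g$ny * g$nz, 8)
  e <- 0
  for (k in 1:g$nz) for (j in 1:g$ny) for (i in 1:g$nx) {
    e <- e + 1
    out[e, ] <- c(g$idx(i, j, k), g$idx(i + 1, j, k),
                  g$idx(i + 1, j + 1, k), g$idx(i, j + 1, k),
                  g$idx(i, j, k + 1), g$idx(i + 1, j, k + 1),
                  g$idx(i + 1, j + 1, k + 1), g$idx(i, j + 1, k + 1))
  }
  out
}

#' Build the parametric normative template model
#'
#' Constructs a straight (normative, curvature-free) stack of hexahedral
#' vertebral-body blocks with intervening IVD blocks that share interface
#' nodes (tied contact), a posterior spring chain standing in for the
#' posterior bony elements, and seven tension-only ligament springs per
#' adjacent level pair. The caudal base (L5 inferior endplate) is fully
#' fixed and T1's superior endplate is restricted to vertical translation.
#'
#' @param dims vertebral dimension table ([default_dimension_table()]).
#' @param refinement integer vector `c(nx, ny, nz)` of hexes per body
#'   along depth/width/height; `nx`, `ny`, `nz` must be even and >= 2 so
#'   the four quadrants and the landmark nodes exist. Default `c(4, 4, 2)`.
#' @param posterior_offset distance (mm) of the posterior node chain
#'   behind the body posterior face. Default 15.
#' @param ligament_k,posterior_chain_k,posterior_attach_k nominal spring
#'   stiffnesses (N/mm) before age scaling. The chain default reproduces a
#'   posterior load share of roughly 15% against the disc column.
#' @return A [hex_mesh] object.
#' @export
build_template <- function(dims = default_dimension_table(),
                           refinement = c(4, 4, 2),
                           posterior_offset = 15,
                           ligament_k = 20,
                           posterior_chain_k = 140,
                           posterior_attach_k = 1000) {
  dims <- check_dimension_table(dims)
  nx <- as.integer(refinement[1]); ny <- as.integer(refinement[2])
  nz <- as.integer(refinement[3])
  if (any(c(nx, ny, nz) < 2) || any(c(nx, ny, nz) %% 2 != 0)) {
    stop("refinement must be even and >= 2 along each axis")
  }
  lv <- spine_levels()
  # z extents, built bottom-up: L5 base at z = 0
  z0 <- numeric(17)
  z <- 0
  for (i in 17:1) {
    z0[i] <- z
    z <- z + dims$height[i]
    if (i > 1) z <- z + dims$ivd_height[i - 1]  # disc below level i-1
  }
  nodes <- NULL
  hexes <- NULL
  elem <- NULL
  corner_rows <- list()
  sup_face <- vector("list", 17); names(sup_face) <- lv
  inf_face <- vector("list", 17); names(inf_face) <- lv
  body_grid_idx <- vector("list", 17)  # global node index arrays
  for (i in 1:17) {
    hd <- dims$depth[i] / 2; hw <- dims$width[i] / 2
    g <- box_grid(-hd, hd, -hw, hw, z0[i], z0[i] + dims$height[i], nx, ny, nz)
    off <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <- rbind(nodes, g$nodes)
    hx <- box_hexes(g) + off
    # quadrant labels from element centers: x > 0 anterior, y > 0 left
    cen <- (nodes[hx[, 1], , drop = FALSE] + nodes[hx[, 7], , drop = FALSE]) / 2
    region <- ifelse(cen[, 1] > 0,
                     ifelse(cen[, 2] > 0, "body_ant_left", "body_ant_right"),
                     ifelse(cen[, 2] > 0, "body_post_left", "body_post_right"))
    hexes <- rbind(hexes, hx)
    elem <- rbind(elem, data.frame(structure = "vertebra", level = lv[i],
                                   region = region))
    gi <- local({
      off_ <- off; idx_ <- g$idx
      function(i1, j1, k1) off_ + idx_(i1, j1, k1)
    })
    body_grid_idx[[i]] <- list(gi = gi)
    # landmark-bearing nodes (mid-plane indices exist because nx, ny, nz even)
    mx <- nx / 2 + 1; my <- ny / 2 + 1; mz <- nz / 2 + 1
    corner_rows[[i]] <- data.frame(
      level = lv[i],
      id = c("sup_left", "sup_right", "inf_left", "inf_right",
             "sup_ant", "sup_post", "inf_ant", "inf_post", "centroid"),
      node = c(gi(mx, ny + 1, nz + 1), gi(mx, 1, nz + 1),
               gi(mx, ny + 1, 1), gi(mx, 1, 1),
               gi(nx + 1, my, nz + 1), gi(1, my, nz + 1),
               gi(nx + 1, my, 1), gi(1, my, 1),
               gi(mx, my, mz)))
    # endplate node sets
    kk <- expand.grid(i = 1:(nx + 1), j = 1:(ny + 1))
    sup_face[[i]] <- gi(kk$i, kk$j, nz + 1)
    inf_face[[i]] <- gi(kk$i, kk$j, 1)
  }
  # IVD blocks: ruled hexes between the inferior face of the upper body and
  # the superior face of the lower body (shared nodes = tied contact).
  for (i in 1:16) {
    up <- body_grid_idx[[i]]     # level i (above)
    lo <- body_grid_idx[[i + 1]] # level i+1 (below)
    for (jj in 1:ny) for (ii in 1:nx) {
      bl <- c(lo$gi(ii, jj, nz + 1), lo$gi(ii + 1, jj, nz + 1),
              lo$gi(ii + 1, jj + 1, nz + 1), lo$gi(ii, jj + 1, nz + 1))
      tp <- c(up$gi(ii, jj, 1), up$gi(ii + 1, jj, 1),
              up$gi(ii + 1, jj + 1, 1), up$gi(ii, jj + 1, 1))
      hexes <- rbind(hexes, matrix(c(bl, tp), 1))
      cen <- colMeans(nodes[c(bl, tp), ])
      region <- if (cen[1] > 0) {
        if (cen[2] > 0) "ant_left" else "ant_right"
      } else {
        if (cen[2] > 0) "post_left" else "post_right"
      }
      elem <- rbind(elem, data.frame(structure = "ivd", level = lv[i],
                                     region = region))
    }
  }
  corner_nodes <- do.call(rbind, corner_rows)
  # posterior node chain
  post_node <- integer(17)
  springs <- NULL
  for (i in 1:17) {
    hd <- dims$depth[i] / 2
    zmid <- z0[i] + dims$height[i] / 2
    nodes <- rbind(nodes, c(-hd - posterior_offset, 0, zmid))
    post_node[i] <- nrow(nodes)
    # stiff isotropic arm from the posterior face centre to the chain node
    face_mid <- body_grid_idx[[i]]$gi(1, ny / 2 + 1, nz / 2 + 1)
    springs <- rbind(springs, data.frame(
      node_a = face_mid, node_b = post_node[i],
      stiffness = posterior_attach_k, tension_only = FALSE,
      isotropic = TRUE, label = "posterior"))
  }
  cn <- function(level, id) {
    corner_nodes$node[corner_nodes$level == level & corner_nodes$id == id]
  }
  for (i in 1:16) {
    upper <- lv[i]; lower <- lv[i + 1]
    g_up <- body_grid_idx[[i]]; g_lo <- body_grid_idx[[i + 1]]
    # posterior chain (bilateral, carries compression)
    springs <- rbind(springs, data.frame(
      node_a = post_node[i + 1], node_b = post_node[i],
      stiffness = posterior_chain_k, tension_only = FALSE,
      isotropic = FALSE, label = "posterior"))
    # 7 tension-only ligaments per level pair
    lig <- rbind(
      c(cn(lower, "sup_ant"), cn(upper, "inf_ant")),                # ALL
      c(cn(lower, "sup_post"), cn(upper, "inf_post")),              # PLL
      c(cn(lower, "sup_left"), cn(upper, "inf_left")),              # ITL left
      c(cn(lower, "sup_right"), cn(upper, "inf_right")),            # ITL right
      c(post_node[i + 1], post_node[i]),                            # LF/ISL
      c(g_lo$gi(1, ny + 1, nz + 1), g_up$gi(1, ny + 1, 1)),         # CL left
      c(g_lo$gi(1, 1, nz + 1), g_up$gi(1, 1, 1)))                   # CL right
    springs <- rbind(springs, data.frame(
      node_a = lig[, 1], node_b = lig[, 2], stiffness = ligament_k,
      tension_only = TRUE, isotropic = FALSE, label = "ligament"))
  }
  springs$stiffness0 <- springs$stiffness
  constraints <- matrix(FALSE, nrow(nodes), 3)
  constraints[inf_face[["L5"]], ] <- TRUE          # caudal base fully fixed
  constraints[sup_face[["T1"]], 1:2] <- TRUE       # T1: vertical translation only
  rownames(nodes) <- NULL
  new_hex_mesh(nodes, hexes, elem, springs, constraints, corner_nodes,
               sup_face, inf_face,
               meta = list(dims = dims, refinement = c(nx, ny, nz)))
}

#' Extract mesh-borne landmarks
#'
#' Returns the 153 landmark coordinates carried by the mesh's
#' corner-node map at the current node positions.
#'
#' @param model a `hex_mesh`.
#' @return A `landmark_set`.
#' @export
mesh_landmarks <- function(model) {
  stopifnot(inherits(model, "hex_mesh"))
  p <- model$nodes[model$corner_nodes$node, , drop = FALSE]
  landmark_set(data.frame(level = model$corner_nodes$level,
                          id = model$corner_nodes$id,
                          x = p[, 1], y = p[, 2], z = p[, 3]))
}

# ---- mesh quality ----------------------------------------------------------

HEX_CORNER_EDGES <- list(c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
                         c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))
HEX_FACES <- rbind(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
                   c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
HEX_EDGES <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                   c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                   c(1, 5), c(2, 6), c(3, 7), c(4, 8))

unit <- function(v) v / sqrt(sum(v^2))

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}

hex_quality_one <- function(x) {
  # x: 8 x 3 corner coordinates
  jac <- Inf
  for (c0 in 1:8) {
    adj <- HEX_CORNER_EDGES[[c0]]
    e1 <- unit(x[adj[1], ] - x[c0, ])
    e2 <- unit(x[adj[2], ] - x[c0, ])
    e3 <- unit(x[adj[3], ] - x[c0, ])
    jac <- min(jac, det(rbind(e1, e2, e3)))
  }
  elen <- sqrt(rowSums((x[HEX_EDGES[, 1], ] - x[HEX_EDGES[, 2], ])^2))
  aspect <- max(elen) / min(elen)
  skew <- 0; warp <- 0; qmin <- 180; qmax <- 0
  for (f in 1:6) {
    q <- x[HEX_FACES[f, ], , drop = FALSE]
    d1 <- q[3, ] - q[1, ]; d2 <- q[4, ] - q[2, ]
    skew <- max(skew, abs(angle_deg(d1, d2) - 90))
    # warpage: angle between the two triangle planes for each diagonal split
    for (sp in list(list(c(1, 2, 3), c(1, 3, 4)), list(c(1, 2, 4), c(2, 3, 4)))) {
      n1 <- cross3(q[sp[[1]][2], ] - q[sp[[1]][1], ], q[sp[[1]][3], ] - q[sp[[1]][1], ])
      n2 <- cross3(q[sp[[2]][2], ] - q[sp[[2]][1], ], q[sp[[2]][3], ] - q[sp[[2]][1], ])
      warp <- max(warp, angle_deg(n1, n2))
    }
    for (c0 in 1:4) {
      a <- q[(c0 %% 4) + 1, ] - q[c0, ]
      b <- q[((c0 + 2) %% 4) + 1, ] - q[c0, ]
      ang <- angle_deg(a, b)
      qmin <- min(qmin, ang); qmax <- max(qmax, ang)
    }
  }
  c(jacobian = jac, aspect = aspect, skewness = skew, warpage = warp,
    quad_min = qmin, quad_max = qmax)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Hexahedral mesh quality metrics
#'
#' Per-element metrics: scaled Jacobian (minimum over the 8 corners of the
#' determinant of the unit-normalized edge triad), edge aspect ratio,
#' skewness (max deviation of the face-diagonal angle from 90 degrees),
#' warpage (max angle between the two triangle planes of each split quad
#' face), and min/max quad interior angles over the 6 faces.
#'
#' @param model a `hex_mesh`.
#' @return Object of class `quality_report`: data frame of per-element
#'   metrics plus an `inverted` attribute listing elements with
#'   non-positive scaled Jacobian.
#' @export
mesh_quality <- function(model) {
  stopifnot(inherits(model, "hex_mesh"))
  m <- t(vapply(seq_len(nrow(model$hexes)), function(e) {
    hex_quality_one(model$nodes[model$hexes[e, ], , drop = FALSE])
  }, numeric(6)))
  rep <- as.data.frame(m)
  inverted <- which(rep$jacobian <= 0)
  if (length(inverted)) {
    warning("inverted element(s) (scaled Jacobian <= 0): ",
            paste(utils::head(inverted, 10), collapse = ", "))
  }
  attr(rep, "inverted") <- inverted
  class(rep) <- c("quality_report", "data.frame")
  rep
}

#' Default mesh-quality acceptance thresholds
#'
#' Scaled Jacobian >= 0.5, aspect <= 5, skewness <= 60 deg, warpage <= 40
#' deg, quad min angle >= 30 deg, quad max angle <= 150 deg.
#'
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function() {
  list(jacobian = 0.5, aspect = 5, skewness = 60, warpage = 40,
       quad_min = 30, quad_max = 150)
}

#' Check a quality report against acceptance thresholds
#'
#' @param report a `quality_report` from [mesh_quality()].
#' @param thresholds named list, see [quality_thresholds()].
#' @param floor minimum acceptable pass-fraction per criterion (default
#'   0.97).
#' @return List with `fractions` (named pass-fractions in \[0, 1\]),
#'   `pass` (per-criterion logical), and `overall`.
#' @export
check_quality <- function(report, thresholds = quality_thresholds(),
                          floor = 0.97) {
  fr <- c(jacobian = mean(report$jacobian >= thresholds$jacobian),
          aspect = mean(report$aspect <= thresholds$aspect),
          skewness = mean(report$skewness <= thresholds$skewness),
          warpage = mean(report$warpage <= thresholds$warpage),
          quad_min = mean(report$quad_min >= thresholds$quad_min),
          quad_max = mean(report$quad_max <= thresholds$quad_max))
  pass <- fr >= floor
  list(fractions = fr, pass = pass, overall = all(pass))
}
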