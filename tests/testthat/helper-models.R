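# shared fixtures, built in code

# rectangular block mesh with no springs; E in MPa
make_block <- function(lx = 1, ly = 1, lz = 1, nx = 1, ny = 1, nz = 1,
                       E = 100, nu = 0.3) {
  g <- spinegrowth:::box_grid(0, lx, 0, ly, 0, lz, nx, ny, nz)
  hexes <- spinegrowth:::box_hexes(g)
  elem <- data.frame(structure = "vertebra", level = "T1",
                     region = "body_ant_left", E = E, nu = nu)
  elem <- elem[rep(1, nrow(hexes)), ]
  rownames(elem) <- NULL
  springs <- data.frame(node_a = integer(0), node_b = integer(0),
                        stiffness = numeric(0), tension_only = logical(0),
                        isotropic = logical(0), label = character(0))
  con <- matrix(FALSE, nrow(g$nodes), 3)
  spinegrowth:::new_hex_mesh(g$nodes, hexes, elem, springs, con,
                             NULL, list(), list())
}

# pin rigid-body modes of a free-floating block: one node fully fixed,
# one along +x fixed in y,z, one in the xy plane fixed in z
pin_rigid_modes <- function(model) {
  nd <- model$nodes
  origin <- which(rowSums(abs(nd)) == min(rowSums(abs(nd))))[1]
  on_x <- which(nd[, 2] == nd[origin, 2] & nd[, 3] == nd[origin, 3] &
                  nd[, 1] != nd[origin, 1])[1]
  in_xy <- which(nd[, 3] == nd[origin, 3] & nd[, 2] != nd[origin, 2])[1]
  model$constraints[origin, ] <- TRUE
  model$constraints[on_x, c(2, 3)] <- TRUE
  model$constraints[in_xy, 3] <- TRUE
  model
}

# memoized expensive fixtures (shared within a test run)
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_template <- function() {
  fixture("small_template", function() build_template(refinement = c(2, 2, 2)))
}

default_patient <- function() {
  fixture("default_patient", function() generate_patient(synth_spec()))
}

# default patient morphed to a small model with materials
small_patient_model <- function() {
  fixture("small_patient_model", function() {
    pat <- default_patient()
    m <- morph_model(small_template(), pat$landmarks)
    assign_materials(m, default_material_cards(pat$profile$age), pat$profile)
  })
}
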