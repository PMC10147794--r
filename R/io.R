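#' Export a mesh to legacy VTK unstructured-grid format
#'
#' Writes an ASCII legacy VTK file with hexahedron cells (type 12) and
#' per-cell data arrays `structure` (1 = vertebra, 2 = ivd), `level`
#' (ordinal 1-17), `region` (index into [region_ids()] for body quadrants,
#' 20 + quadrant index for IVD quadrants) and, if materials are assigned,
#' `E`. Springs and constraints are not representable in this format; use
#' [write_model_json()] for a lossless round trip.
#'
#' @param model a `hex_mesh`.
#' @param path output `.vtk` path.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(model, path) {
  stopifnot(inherits(model, "hex_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "spinegrowth hexahedral spine model",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  nn <- nrow(model$nodes); ne <- nrow(model$hexes)
  writeLines(sprintf("POINTS %d double", nn), con)
  writeLines(apply(format(model$nodes, trim = TRUE, digits = 10), 1, paste,
                   collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9), con)
  writeLines(apply(cbind(8L, model$hexes - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS structure int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(ifelse(model$elem$structure == "vertebra", 1L, 2L)),
             con)
  writeLines(c("SCALARS level int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(level_index(model$elem$level)), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  reg <- ifelse(model$elem$structure == "vertebra",
                match(model$elem$region, region_ids()),
                20L + match(model$elem$region,
                            c("ant_left", "ant_right", "post_left",
                              "post_right")))
  writeLines(as.character(reg), con)
  if (!is.null(model$elem$E)) {
    writeLines(c("SCALARS E double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(model$elem$E, trim = TRUE, digits = 8), con)
  }
  invisible(path)
}

#' Lossless JSON serialization of a mesh model
#'
#' Serializes nodes, connectivity, element labels, springs, constraints
#' and the corner-node map so a model can be reloaded exactly (to double
#' precision) by [read_model_json()].
#'
#' @param model a `hex_mesh`.
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "hex_mesh"))
  obj <- list(nodes = model$nodes, hexes = model$hexes,
              elem = model$elem, springs = model$springs,
              constraints = model$constraints,
              corner_nodes = model$corner_nodes,
              sup_face = model$sup_face, inf_face = model$inf_face)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_model_json
#' @return For `read_model_json`: the reconstructed `hex_mesh`.
#' @export
read_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_hex_mesh(nodes = as.matrix(o$nodes),
               hexes = matrix(as.integer(as.matrix(o$hexes)),
                              nrow = nrow(o$hexes)),
               elem = as.data.frame(o$elem),
               springs = as.data.frame(o$springs),
               constraints = matrix(as.logical(as.matrix(o$constraints)),
                                    nrow = nrow(o$constraints)),
               corner_nodes = as.data.frame(o$corner_nodes),
               sup_face = lapply(o$sup_face, as.integer),
               inf_face = lapply(o$inf_face, as.integer))
}

#' Write a trajectory's outputs to a directory
#'
#' Emits `indices.csv`, `quadrant_stress.csv`, one VTK mesh per recorded
#' timepoint, and `manifest.json`.
#'
#' @param traj a `growth_trajectory` from [simulate_growth()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "growth_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(traj$indices, file.path(dir, "indices.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(traj$quadrant_stress, file.path(dir, "quadrant_stress.csv"),
                   row.names = FALSE, quote = FALSE)
  for (t in names(traj$models)) {
    write_vtk(traj$models[[t]], file.path(dir, sprintf("model_t%s.vtk", t)))
  }
  jsonlite::write_json(traj$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
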