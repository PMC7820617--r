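#' Node table CSV I/O
#'
#' Node tables are plain CSV with columns `patient_id, node_id, x_mm, y_mm,
#' z_mm, space, level, side, surgery` (extra columns such as
#' `displacement_mm` pass through).
#'
#' @param nodes node table data.frame.
#' @param path file path.
#' @export
write_nodes_csv <- function(nodes, path) {
  utils::write.csv(nodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nodes_csv
#' @export
read_nodes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an atlas as NRRD label map plus JSON level table
#'
#' @param atlas a `level_atlas`.
#' @param path output `.nrrd` path; the level table goes to a `.json`
#'   sidecar with the same stem.
#' @export
write_atlas <- function(atlas, path) {
  write_nrrd(atlas$labels + 0.0, atlas$grid, path)
  side <- sub("\\.nrrd$", ".json", path)
  jsonlite::write_json(
    list(levels = atlas$table,
         grid = list(shape = atlas$grid$shape, spacing = atlas$grid$spacing,
                     origin = atlas$grid$origin, orientation = "LPS")),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  vol <- read_nrrd(path)
  side <- jsonlite::read_json(sub("\\.nrrd$", ".json", path),
                              simplifyVector = TRUE)
  structure(list(grid = vol$grid,
                 labels = array(as.integer(round(vol$values)),
                                dim = vol$grid$shape),
                 table = as.data.frame(side$levels)),
            class = "level_atlas")
}

#' Write a density map as NRRD plus JSON metadata sidecar
#'
#' @param map a `density_map`.
#' @param path output `.nrrd` path.
#' @export
write_density <- function(map, path) {
  write_nrrd(map$values, map$grid, path)
  meta <- map$meta
  meta$config <- unclass(meta$config)
  jsonlite::write_json(meta, sub("\\.nrrd$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a displacement field as 3-component NRRD
#'
#' @param field a `displacement_field`.
#' @param path output `.nrrd` path.
#' @export
write_dvf <- function(field, path) {
  write_nrrd(field$vectors, field$grid, path)
  invisible(path)
}

#' @rdname write_dvf
#' @param direction direction tag to attach on read.
#' @export
read_dvf <- function(path, direction = "native_to_template") {
  vol <- read_nrrd(path)
  displacement_field(vol$values, vol$grid, direction)
}
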