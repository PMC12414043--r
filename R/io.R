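# Plain-text interchange: ASCII PLY for meshes, CSV for per-node metric
# fields, JSON for ground truth and camera transforms.

#' Write / read a surface mesh as ASCII PLY
#'
#' Node region tags ride along as an integer vertex property `region`
#' (0 = dome, 1 = parent_vessel); adjacency, normals and the edge graph are
#' rebuilt on read.
#'
#' @param mesh an `aneurysm_mesh`.
#' @param path file path (conventionally `.ply`).
#' @export
write_mesh_ply <- function(mesh, path) {
  n <- nrow(mesh$coords); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               "property uchar region",
               sprintf("element face %d", m),
               "property list uchar int vertex_indices",
               "end_header"), con)
  reg <- as.integer(mesh$region == "parent_vessel")
  writeLines(paste(format(mesh$coords[, 1], digits = 9),
                   format(mesh$coords[, 2], digits = 9),
                   format(mesh$coords[, 3], digits = 9), reg), con)
  writeLines(paste(3L, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vtx <- utils::read.table(text = lines[(hdr_end + 1):(hdr_end + nv)])
  fac <- utils::read.table(text = lines[(hdr_end + nv + 1):(hdr_end + nv + nf)])
  tris <- as.matrix(fac[, 2:4]) + 1L
  storage.mode(tris) <- "integer"
  dimnames(tris) <- NULL
  mesh <- structure(
    list(coords = as.matrix(vtx[, 1:3]),
         triangles = tris,
         region = factor(ifelse(vtx[, 4] == 1, "parent_vessel", "dome"),
                         levels = c("dome", "parent_vessel")),
         adjacency = NULL, normals = NULL),
    class = "aneurysm_mesh")
  dimnames(mesh$coords) <- NULL
  mesh$adjacency <- mesh_adjacency(mesh)
  mesh$normals <- mesh_node_normals(mesh)
  mesh$graph <- mesh_graph(mesh)
  validate_mesh(mesh)
  mesh
}

#' Write per-node metric fields as CSV
#'
#' One row per node, one column per metric; units are recorded in a header
#' comment line.
#'
#' @param fields named list of `metric_field`s (see
#'   [compute_metric_fields()]).
#' @param path CSV path.
#' @export
write_metrics_csv <- function(fields, path) {
  units <- vapply(fields, function(f) f$units, character(1))
  df <- as.data.frame(lapply(fields, function(f) f$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(names(units), units, sep = "=", collapse = ", ")), con)
  utils::write.csv(cbind(node_id = seq_len(nrow(df)), df), con, row.names = FALSE)
  invisible(path)
}

#' Write / read generator ground truth as JSON
#' @param truth a `ground_truth` (from [generate_wss_series()]).
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$thin_nodes <- as.integer(truth$thin_nodes)
  class(truth) <- "ground_truth"
  truth
}

#' Write / read a camera transform as JSON
#' @param camera an `aneuwall_camera`.
#' @param path JSON path.
#' @export
write_camera_json <- function(camera, path) {
  jsonlite::write_json(unclass(camera), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  cam <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_camera(lookat = cam$lookat, direction = cam$direction,
              up = cam$up, pixels_per_mm = cam$pixels_per_mm)
}
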