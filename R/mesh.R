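# Synthetic aneurysm geometry: a spherical dome fused to an open parent-vessel
# cylinder, built as a jittered surface of revolution so the two parts share
# the neck ring and the mesh is edge-connected by construction.

#' Resolution presets for [generate_aneurysm_mesh()]
#'
#' Each preset fixes the number of azimuthal columns (`n_theta`), dome rings
#' (`n_dome`) and vessel rings (`n_vessel`). The resulting node count is
#' `n_theta * (n_dome + n_vessel) + 1` (the extra node is the dome apex):
#' `coarse` = 481, `medium` = 1081, `fine` = 1921 nodes.
#'
#' @param name one of `"coarse"`, `"medium"`, `"fine"`.
#' @return list with `n_theta`, `n_dome`, `n_vessel`, `nodes`.
#' @export
mesh_resolution_preset <- function(name = c("medium", "coarse", "fine")) {
  name <- match.arg(name)
  p <- switch(name,
    coarse = list(n_theta = 24L, n_dome = 14L, n_vessel = 6L),
    medium = list(n_theta = 36L, n_dome = 21L, n_vessel = 9L),
    fine   = list(n_theta = 48L, n_dome = 28L, n_vessel = 12L)
  )
  p$nodes <- p$n_theta * (p$n_dome + p$n_vessel) + 1L
  p
}

#' Generate a synthetic aneurysm surface mesh
#'
#' Builds a triangulated aneurysm dome (a spherical cap of radius
#' `dome_radius_mm`) fused onto an open parent-vessel cylinder of radius
#' `vessel_radius_mm`, with coordinates in millimetres. Node positions are
#' jittered tangentially (in the parametric domain, so every node stays
#' exactly on the analytic surface) to avoid a perfectly regular
#' triangulation; the jitter is seeded and the whole construction is
#' deterministic for fixed inputs.
#'
#' The vessel axis is the z-axis: the cylinder spans `z` in
#' `[-vessel_length_mm, 0]` and the dome sits above the neck plane `z = 0`
#' with its apex at `z = sqrt(R^2 - r^2) + R`.
#'
#' @param dome_radius_mm dome (sphere) radius in mm; must exceed
#'   `vessel_radius_mm`.
#' @param vessel_radius_mm parent-vessel radius in mm.
#' @param resolution a preset name (see [mesh_resolution_preset()]) or a list
#'   with integer fields `n_theta`, `n_dome`, `n_vessel`. Resolutions
#'   yielding fewer than 200 nodes are rejected.
#' @param seed integer seed for the tangential jitter.
#' @param vessel_length_mm cylinder length in mm.
#' @param jitter relative jitter amplitude (fraction of the local node
#'   spacing); 0 gives a perfectly regular mesh.
#' @return an object of class `aneurysm_mesh`: a list with
#'   \describe{
#'     \item{coords}{n x 3 matrix of node coordinates (mm)}
#'     \item{triangles}{m x 3 integer matrix of node indices, outward winding}
#'     \item{region}{factor per node, levels `dome`, `parent_vessel`}
#'     \item{adjacency}{list of integer neighbour vectors per node}
#'     \item{normals}{n x 3 matrix of outward unit node normals}
#'   }
#' @export
generate_aneurysm_mesh <- function(dome_radius_mm = 2.5,
                                   vessel_radius_mm = 1.5,
                                   resolution = "medium",
                                   seed = 1L,
                                   vessel_length_mm = 8,
                                   jitter = 0.15) {
  if (dome_radius_mm <= 0 || vessel_radius_mm <= 0 || vessel_length_mm <= 0)
    stop("radii and vessel length must be positive")
  if (vessel_radius_mm >= dome_radius_mm)
    stop("vessel_radius_mm must be smaller than dome_radius_mm (the dome must overhang the neck)")
  if (is.character(resolution)) resolution <- mesh_resolution_preset(resolution)
  n_theta <- as.integer(resolution$n_theta)
  n_dome <- as.integer(resolution$n_dome)
  n_vessel <- as.integer(resolution$n_vessel)
  if (any(c(n_theta, n_dome, n_vessel) < 3L))
    stop("degenerate resolution: need at least 3 subdivisions in every direction")
  n_nodes <- n_theta * (n_dome + n_vessel) + 1L
  if (n_nodes < 200L)
    stop("degenerate resolution: mesh would have ", n_nodes, " nodes (< 200)")

  R <- dome_radius_mm
  rv <- vessel_radius_mm
  h <- sqrt(R^2 - rv^2)           # sphere centre height above the neck plane
  phi_max <- acos(-h / R)          # polar angle of the neck ring
  s_dome <- R * phi_max            # arc length pole -> neck
  s_total <- s_dome + vessel_length_mm

  n_rings <- n_dome + n_vessel
  # ring arc-length positions: dome rings end exactly at the neck (ring n_dome)
  s_rings <- c(seq_len(n_dome) / n_dome * s_dome,
               s_dome + seq_len(n_vessel) / n_vessel * vessel_length_mm)
  theta0 <- (seq_len(n_theta) - 1L) / n_theta * 2 * pi

  set.seed(derive_seed(seed, 1L, stream = 11L))
  ds <- s_total / n_rings
  dtheta <- 2 * pi / n_theta
  # parametric jitter; neck ring and open bottom ring stay on their circles
  s_mat <- matrix(rep(s_rings, each = n_theta), n_theta, n_rings)
  t_mat <- matrix(rep(theta0, n_rings), n_theta, n_rings)
  if (jitter > 0) {
    s_jit <- matrix(stats::rnorm(n_theta * n_rings, 0, jitter * ds), n_theta, n_rings)
    s_jit <- pmin(pmax(s_jit, -0.45 * ds), 0.45 * ds)
    s_jit[, n_dome] <- 0          # neck ring shared by dome and vessel
    s_jit[, n_rings] <- 0         # open end of the vessel
    t_jit <- matrix(stats::rnorm(n_theta * n_rings, 0, jitter * dtheta), n_theta, n_rings)
    t_jit <- pmin(pmax(t_jit, -0.45 * dtheta), 0.45 * dtheta)
    s_mat <- s_mat + s_jit
    t_mat <- t_mat + t_jit
  }

  s_v <- as.vector(s_mat)          # node order: ring-major is column-major here
  t_v <- as.vector(t_mat)
  on_dome <- s_v < s_dome
  phi <- pmin(s_v, s_dome) / R
  coords <- matrix(0, n_theta * n_rings, 3)
  coords[on_dome, 1] <- R * sin(phi[on_dome]) * cos(t_v[on_dome])
  coords[on_dome, 2] <- R * sin(phi[on_dome]) * sin(t_v[on_dome])
  coords[on_dome, 3] <- h + R * cos(phi[on_dome])
  coords[!on_dome, 1] <- rv * cos(t_v[!on_dome])
  coords[!on_dome, 2] <- rv * sin(t_v[!on_dome])
  coords[!on_dome, 3] <- -(s_v[!on_dome] - s_dome)
  apex <- c(0, 0, h + R)
  coords <- rbind(coords, apex)
  dimnames(coords) <- NULL
  n_all <- nrow(coords)
  apex_id <- n_all

  # node index of column k (1..n_theta) on ring r (1..n_rings)
  nid <- function(k, r) (r - 1L) * n_theta + k
  k1 <- seq_len(n_theta)
  k2 <- c(2:n_theta, 1L)
  # apex fan to ring 1 (winding chosen outward, checked and fixed below)
  tris <- cbind(rep(apex_id, n_theta), nid(k1, 1L), nid(k2, 1L))
  for (r in seq_len(n_rings - 1L)) {
    up1 <- nid(k1, r); up2 <- nid(k2, r)
    lo1 <- nid(k1, r + 1L); lo2 <- nid(k2, r + 1L)
    tris <- rbind(tris, cbind(up1, lo1, lo2), cbind(up1, lo2, up2))
  }
  storage.mode(tris) <- "integer"
  dimnames(tris) <- NULL

  # enforce outward orientation (positive mean dot of face normal with the
  # outward radial/apex direction)
  fc <- (coords[tris[, 1], ] + coords[tris[, 2], ] + coords[tris[, 3], ]) / 3
  fn <- cross3(coords[tris[, 2], ] - coords[tris[, 1], ],
               coords[tris[, 3], ] - coords[tris[, 1], ])
  outward <- fc
  dome_face <- fc[, 3] > 0
  outward[dome_face, 3] <- fc[dome_face, 3] - h
  outward[!dome_face, 3] <- 0
  if (mean(rowSums(fn * outward)) < 0) tris <- tris[, c(1L, 3L, 2L)]

  mesh <- structure(
    list(coords = coords, triangles = tris,
         region = factor(ifelse(coords[, 3] > 1e-9, "dome", "parent_vessel"),
                         levels = c("dome", "parent_vessel")),
         adjacency = NULL, normals = NULL),
    class = "aneurysm_mesh")
  mesh$adjacency <- mesh_adjacency(mesh)
  mesh$normals <- mesh_node_normals(mesh)
  mesh$graph <- mesh_graph(mesh)
  validate_mesh(mesh)
  mesh
}

#' Per-node adjacency lists from the triangle table
#' @param mesh an `aneurysm_mesh`.
#' @return list of sorted integer neighbour vectors.
#' @export
mesh_adjacency <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$coords))))
}

#' Outward area-weighted node normals
#' @param mesh an `aneurysm_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_node_normals <- function(mesh) {
  tr <- mesh$triangles
  p <- mesh$coords
  fn <- cross3(p[tr[, 2], ] - p[tr[, 1], ], p[tr[, 3], ] - p[tr[, 1], ]) / 2
  acc <- matrix(0, nrow(p), 3)
  for (j in 1:3) {
    idx <- tr[, j]
    acc[, 1] <- acc[, 1] + tabulate_weighted(idx, fn[, 1], nrow(p))
    acc[, 2] <- acc[, 2] + tabulate_weighted(idx, fn[, 2], nrow(p))
    acc[, 3] <- acc[, 3] + tabulate_weighted(idx, fn[, 3], nrow(p))
  }
  normalize_rows(acc)
}

#' Weighted tabulate: sum of `w` grouped by integer index `idx`
#' @keywords internal
tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Validate structural invariants of a surface mesh
#'
#' Checks that triangle indices are valid, coordinates are finite, every node
#' has at least three neighbours and the mesh is edge-connected.
#' @param mesh an `aneurysm_mesh`.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_mesh <- function(mesh) {
  n <- nrow(mesh$coords)
  if (!all(is.finite(mesh$coords))) stop("non-finite node coordinates")
  if (min(mesh$triangles) < 1L || max(mesh$triangles) > n)
    stop("triangle indices out of range")
  deg <- lengths(mesh$adjacency)
  if (any(deg < 3L)) stop("node(s) with fewer than 3 neighbours: ",
                          paste(utils::head(which(deg < 3L)), collapse = ", "))
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L) stop("mesh is not edge-connected")
  invisible(TRUE)
}

#' igraph representation of the mesh edge graph (edge weights = lengths in mm)
#'
#' Cached on the mesh object (`mesh$graph`) when present.
#' @keywords internal
mesh_graph <- function(mesh) {
  if (!is.null(mesh$graph)) return(mesh$graph)
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- row_norms(mesh$coords[e[, 1], , drop = FALSE] - mesh$coords[e[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w)
  if (igraph::vcount(g) < nrow(mesh$coords))
    g <- igraph::add_vertices(g, nrow(mesh$coords) - igraph::vcount(g))
  g
}

#' Geodesic (edge-graph) distances from a set of source nodes
#'
#' Shortest-path distance along mesh edges, weighted by Euclidean edge length.
#' Returns, for every node, the distance to the nearest source.
#'
#' @param mesh an `aneurysm_mesh`.
#' @param sources integer node indices.
#' @return numeric vector of length `n_nodes` (mm).
#' @export
geodesic_distance <- function(mesh, sources) {
  if (length(sources) == 0L) return(rep(Inf, nrow(mesh$coords)))
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = sources, to = igraph::V(g))
  apply(d, 2, min)
}

#' @export
print.aneurysm_mesh <- function(x, ...) {
  cat("aneurysm_mesh:", nrow(x$coords), "nodes,", nrow(x$triangles), "triangles;",
      sum(x$region == "dome"), "dome /", sum(x$region == "parent_vessel"),
      "parent-vessel nodes\n")
  invisible(x)
}
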