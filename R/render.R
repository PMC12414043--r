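# Intraoperative-style rendering of the aneurysm surface: an orthographic
# camera, a z-buffered triangle rasteriser, and two colour clusters (red for
# thin wall, pinkish-purple for normal wall) with seeded CIELAB noise.
# Pixels are labelled by the nearest (max-barycentric) vertex of the covering
# triangle, so with a pixel pitch well below the node spacing the rendered
# ground-truth mask and the mesh labels round-trip exactly.

#' Orthographic camera for rendering and mask projection
#'
#' @param lookat 3-vector (mm): scene point mapped to the image centre.
#' @param direction unit-ish 3-vector: viewing direction (camera looks along
#'   it); default looks down the vessel axis at the dome from above.
#' @param up approximate image-up direction.
#' @param pixels_per_mm image scale.
#' @return list of class `aneuwall_camera` with an orthonormal frame
#'   (`right`, `up`, `direction`), `lookat` and `pixels_per_mm`.
#' @export
make_camera <- function(lookat = c(0, 0, 3),
                        direction = c(0, 0, -1),
                        up = c(0, 1, 0),
                        pixels_per_mm = 40) {
  dirv <- direction / sqrt(sum(direction^2))
  right <- cross3(dirv, up)
  if (sqrt(sum(right^2)) < 1e-9) stop("up direction parallel to viewing direction")
  right <- right / sqrt(sum(right^2))
  upv <- cross3(right, dirv)
  structure(list(lookat = lookat, direction = dirv, right = right, up = upv,
                 pixels_per_mm = pixels_per_mm),
            class = "aneuwall_camera")
}

#' Project 3D points to continuous image coordinates
#'
#' @param pts n x 3 matrix (mm).
#' @param camera an `aneuwall_camera`.
#' @param image_size `c(height, width)` in pixels.
#' @return data.frame with `u` (column), `v` (row, top-down) and `depth`
#'   (mm along the viewing direction; smaller = nearer).
#' @export
project_points <- function(pts, camera, image_size) {
  rel <- sweep(as.matrix(pts), 2, camera$lookat)
  u <- rel %*% camera$right * camera$pixels_per_mm + (image_size[2] + 1) / 2
  v <- -(rel %*% camera$up) * camera$pixels_per_mm + (image_size[1] + 1) / 2
  data.frame(u = as.vector(u), v = as.vector(v),
             depth = as.vector(rel %*% camera$direction))
}

#' Rasterise the mesh: depth buffer and nearest-vertex label per pixel
#'
#' Front-facing triangles (outward normal opposing the viewing direction)
#' are rasterised with a z-buffer; each covered pixel records the triangle
#' vertex with the largest barycentric weight. A second pass lets every
#' visible front-facing node claim the pixel its projection rounds to
#' (nearest claimant wins), so a node's own pixel always carries that node's
#' label even where the jittered projection folds locally; this is what
#' makes the rendered mask and [project_mask_to_mesh()] round-trip exactly.
#' @keywords internal
rasterize_mesh <- function(mesh, camera, image_size) {
  pr <- project_points(mesh$coords, camera, image_size)
  h <- image_size[1]; w <- image_size[2]
  zbuf <- matrix(Inf, h, w)
  vertex <- matrix(0L, h, w)
  tr <- mesh$triangles
  fn <- cross3(mesh$coords[tr[, 2], ] - mesh$coords[tr[, 1], ],
               mesh$coords[tr[, 3], ] - mesh$coords[tr[, 1], ])
  front <- (fn %*% camera$direction) < 0
  for (t_i in which(as.vector(front))) {
    vid <- tr[t_i, ]
    tu <- pr$u[vid]; tv <- pr$v[vid]; td <- pr$depth[vid]
    c0 <- max(1L, ceiling(min(tu))); c1 <- min(w, floor(max(tu)))
    r0 <- max(1L, ceiling(min(tv))); r1 <- min(h, floor(max(tv)))
    if (c0 > c1 || r0 > r1) next
    px <- rep(c0:c1, each = r1 - r0 + 1L)
    py <- rep(r0:r1, times = c1 - c0 + 1L)
    det <- (tu[2] - tu[1]) * (tv[3] - tv[1]) - (tu[3] - tu[1]) * (tv[2] - tv[1])
    if (abs(det) < 1e-12) next
    l2 <- ((px - tu[1]) * (tv[3] - tv[1]) - (py - tv[1]) * (tu[3] - tu[1])) / det
    l3 <- ((py - tv[1]) * (tu[2] - tu[1]) - (px - tu[1]) * (tv[2] - tv[1])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    px <- px[inside]; py <- py[inside]
    lmat <- cbind(l1[inside], l2[inside], l3[inside])
    depth <- lmat %*% td
    lin <- py + (px - 1L) * h
    closer <- depth < zbuf[lin]
    if (!any(closer)) next
    lin <- lin[closer]
    zbuf[lin] <- depth[closer]
    vertex[lin] <- vid[max.col(lmat[closer, , drop = FALSE], ties.method = "first")]
  }
  # node-claim pass: visible nodes own the pixel they project into
  tol <- visibility_tolerance(camera)
  node_front <- as.vector(mesh$normals %*% camera$direction) < 0
  px <- as.integer(round(pr$u)); py <- as.integer(round(pr$v))
  claim <- which(node_front & px >= 1L & px <= w & py >= 1L & py <= h)
  claim <- claim[pr$depth[claim] <= zbuf[cbind(py[claim], px[claim])] + tol]
  claim <- claim[order(-pr$depth[claim])]   # nearer claimants overwrite
  vertex[cbind(py[claim], px[claim])] <- claim
  list(zbuf = zbuf, vertex = vertex, projections = pr)
}

#' Depth tolerance (mm) for deciding node visibility against the z-buffer
#' @keywords internal
visibility_tolerance <- function(camera) 2 / camera$pixels_per_mm

#' Default colour clusters for the synthetic intraoperative image
#'
#' 8-bit sRGB cluster centres: translucent-red thin wall, pinkish-purple
#' normal wall, and a dark surgical-field background.
#' @export
intraop_colours <- function() {
  list(thin = c(170L, 40L, 50L),
       wall = c(190L, 120L, 160L),
       background = c(45L, 60L, 55L))
}

#' Render a synthetic intraoperative-style image with ground truth
#'
#' Rasterises the mesh through `camera`; pixels whose nearest visible vertex
#' belongs to `thin_nodes` are drawn from the red thin-wall colour cluster,
#' other wall pixels from the pinkish-purple cluster, background from a dark
#' cluster. With `colour_noise_sd > 0`, seeded Gaussian noise is added in
#' CIELAB and converted back to 8-bit sRGB; with zero noise the cluster
#' centre bytes are written untouched. The returned `mask` is the exact
#' ground-truth set of thin-wall pixels.
#'
#' @param mesh an `aneurysm_mesh`.
#' @param thin_nodes integer node indices of the thin patch.
#' @param camera an `aneuwall_camera`.
#' @param image_size `c(height, width)` pixels.
#' @param colours list with 8-bit RGB triples `thin`, `wall`, `background`.
#' @param colour_noise_sd CIELAB noise standard deviation.
#' @param seed integer seed for the colour noise.
#' @return list with `image` (class `rgb_image`), `mask` (logical matrix),
#'   `camera`, `zbuf` (depth buffer, mm).
#' @export
render_intraop_image <- function(mesh, thin_nodes, camera = make_camera(),
                                 image_size = c(440L, 440L),
                                 colours = intraop_colours(),
                                 colour_noise_sd = 2.5,
                                 seed = 1L) {
  ras <- rasterize_mesh(mesh, camera, image_size)
  if (all(ras$vertex == 0L))
    stop("camera misses the mesh entirely: no triangle projects into frame")
  thin_flag <- logical(nrow(mesh$coords))
  thin_flag[thin_nodes] <- TRUE
  covered <- ras$vertex > 0L
  mask <- covered & matrix(thin_flag[pmax(ras$vertex, 1L)],
                           image_size[1], image_size[2])

  h <- image_size[1]; w <- image_size[2]
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(colours$background[ch], h, w)
    plane[covered] <- colours$wall[ch]
    plane[mask] <- colours$thin[ch]
    img[, , ch] <- plane
  }
  if (colour_noise_sd > 0) {
    set.seed(derive_seed(seed, 17L, stream = 41L))
    flat <- matrix(as.vector(img), ncol = 3) / 255
    lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
    lab <- lab + matrix(stats::rnorm(length(lab), 0, colour_noise_sd), ncol = 3)
    lab[, 1] <- pmin(pmax(lab[, 1], 0), 100)
    srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
    srgb <- pmin(pmax(srgb, 0), 1)
    img <- array(as.integer(round(srgb * 255)), dim = c(h, w, 3))
  }
  list(image = rgb_image(img), mask = mask, camera = camera, zbuf = ras$zbuf)
}
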