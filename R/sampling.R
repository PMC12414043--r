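# Regional sampling: map thin/normal labels onto mesh nodes (from the
# projected segmentation mask or directly from generator ground truth),
# select conservative centre points well inside each region, and extract
# fixed-size nearest-node patches into the long-format sample table that
# feeds the mixed model.

#' Build node labels from a known thin node set
#'
#' @param mesh an `aneurysm_mesh`.
#' @param thin_nodes integer indices of thin nodes (dome nodes only; any
#'   parent-vessel index is dropped, mirroring the rule that colour matches
#'   on the parent vessel are discarded).
#' @param provenance provenance string recorded on the result.
#' @return factor of class `node_labels` with levels
#'   `thin`, `normal`, `excluded` (parent vessel).
#' @export
node_labels <- function(mesh, thin_nodes, provenance = "direct ground truth") {
  n <- nrow(mesh$coords)
  lab <- rep("normal", n)
  lab[mesh$region == "parent_vessel"] <- "excluded"
  keep <- intersect(thin_nodes, which(mesh$region == "dome"))
  lab[keep] <- "thin"
  structure(factor(lab, levels = c("thin", "normal", "excluded")),
            provenance = provenance, class = c("node_labels", "factor"))
}

#' Project a segmentation mask onto the mesh
#'
#' A node is provisionally thin iff it is front-facing for the camera, not
#' occluded (its depth matches the rasterised depth buffer within half a
#' pixel footprint), and its projection falls on a mask pixel. Parent-vessel
#' nodes are forced to `excluded` whatever the mask says.
#'
#' @param mask logical image matrix (the segmentation output).
#' @param camera the `aneuwall_camera` used at render/acquisition time.
#' @param mesh an `aneurysm_mesh`.
#' @return a `node_labels` factor with provenance `"projected mask"`.
#' @export
project_mask_to_mesh <- function(mask, camera, mesh) {
  image_size <- dim(mask)
  ras <- rasterize_mesh(mesh, camera, image_size)
  if (all(ras$vertex == 0L)) stop("camera/mesh mismatch: nothing projects into frame")
  pr <- ras$projections
  front <- as.vector(mesh$normals %*% camera$direction) < 0
  px <- as.integer(round(pr$u)); py <- as.integer(round(pr$v))
  inframe <- px >= 1L & px <= image_size[2] & py >= 1L & py <= image_size[1]
  tol <- visibility_tolerance(camera)
  thin <- logical(nrow(mesh$coords))
  idx <- which(front & inframe)
  lin <- cbind(py[idx], px[idx])
  visible <- pr$depth[idx] <= ras$zbuf[lin] + tol
  thin[idx[visible & mask[lin]]] <- TRUE
  node_labels(mesh, which(thin), provenance = "projected mask")
}

#' Erode a labelled region by a geodesic margin
#'
#' Returns the indices of nodes of the given type whose geodesic (edge
#' graph) distance to the nearest node of any other type exceeds
#' `margin_mm`.
#' @keywords internal
erode_region <- function(labels, mesh, type, margin_mm) {
  in_region <- labels == type
  members <- which(in_region)
  if (length(members) == 0L) return(integer())
  frontier <- unique(unlist(mesh$adjacency[members]))
  frontier <- frontier[!in_region[frontier]]
  if (length(frontier) == 0L) return(members)   # region covers the whole mesh
  d <- geodesic_distance(mesh, frontier)
  members[d[members] > margin_mm]
}

#' Select conservative centre points for both region types
#'
#' Each region type (thin, normal) is first eroded by `margin_mm` along the
#' mesh edge graph, so centres sit well inside their region; within the
#' eroded set, centres are chosen to maximise pairwise geodesic separation
#' (exhaustive best pair, then greedy farthest-point additions), with ties
#' broken by lowest node index. The procedure is deterministic; `seed` is
#' accepted for interface stability.
#'
#' @param labels a `node_labels` factor.
#' @param mesh an `aneurysm_mesh`.
#' @param n_per_region centres per region type (default 2, i.e. four
#'   sampling sites in total).
#' @param margin_mm geodesic erosion margin (mm). Choose it at least as
#'   large as the expected radius of a `k`-nearest-node patch so patches
#'   cannot leak across the label boundary.
#' @param seed unused (selection is deterministic); kept in the signature.
#' @param patient_id optional label used in error messages.
#' @return data.frame of class `centre_points`: `region_type`, `region_no`
#'   (thin centres first), `node`, `x`, `y`, `z`.
#' @export
select_centre_points <- function(labels, mesh, n_per_region = 2L,
                                 margin_mm = 1.0, seed = 1L,
                                 patient_id = "patient") {
  pick <- function(type, offset) {
    cand <- erode_region(labels, mesh, type, margin_mm)
    if (length(cand) < n_per_region)
      stop(sprintf("%s: eroded %s region retains %d node(s) (< %d); reduce margin_mm or enlarge the region",
                   patient_id, type, length(cand), n_per_region))
    cand <- sort(cand)
    if (n_per_region == 1L) {
      # deepest candidate: maximise distance to the region boundary
      frontier <- unique(unlist(mesh$adjacency[which(labels == type)]))
      frontier <- frontier[labels[frontier] != type]
      d <- if (length(frontier)) geodesic_distance(mesh, frontier)[cand] else rep(Inf, length(cand))
      sel <- cand[which.max(d)]
    } else {
      g <- mesh_graph(mesh)
      dm <- igraph::distances(g, v = cand, to = cand)
      best <- which(dm == max(dm), arr.ind = TRUE)[1, ]  # lowest indices win
      sel <- cand[sort(best)]
      while (length(sel) < n_per_region) {
        rest <- setdiff(cand, sel)
        dmin <- apply(dm[match(rest, cand), match(sel, cand), drop = FALSE], 1, min)
        sel <- c(sel, rest[which.max(dmin)])
      }
    }
    data.frame(region_type = type, region_no = offset + seq_along(sel),
               node = sel,
               x = mesh$coords[sel, 1], y = mesh$coords[sel, 2],
               z = mesh$coords[sel, 3])
  }
  out <- rbind(pick("thin", 0L), pick("normal", n_per_region))
  out$region_type <- factor(out$region_type, levels = c("normal", "thin"))
  class(out) <- c("centre_points", "data.frame")
  out
}

#' Extract the k nearest nodes around a centre
#'
#' Euclidean nearest-node patch (the centre node itself included when the
#' centre is a node); distance ties resolve to the lowest node index.
#'
#' @param mesh an `aneurysm_mesh`.
#' @param centre integer node index or length-3 coordinate (mm).
#' @param k patch size (default 10).
#' @return integer vector of `k` node indices, nearest first.
#' @export
extract_patch <- function(mesh, centre, k = 10L) {
  if (k > nrow(mesh$coords)) stop("k exceeds the mesh node count")
  pt <- if (length(centre) == 1L) mesh$coords[as.integer(centre), ] else centre
  d <- row_norms(sweep(mesh$coords, 2, pt))
  order(d, seq_along(d))[seq_len(k)]
}

#' Build the long-format regional sample table for a cohort
#'
#' For each patient: label the nodes (from generator ground truth or by
#' projecting a rendered segmentation mask through the render camera),
#' select `n_per_region` centre points per region type, extract the
#' `k`-nearest-node patch around each centre and record all metric values at
#' the patch nodes. With the defaults (2 + 2 centres, k = 10) each patient
#' contributes 40 rows, 20 thin and 20 normal.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param k nodes per patch.
#' @param n_per_region centres per region type per patient.
#' @param margin_mm geodesic erosion margin for centre selection (mm).
#' @param label_source `"truth"` (generator thin node sets) or `"image"`
#'   (render each patient, segment by Delta E at `threshold`, and project
#'   the mask back onto the mesh).
#' @param wssd_mode passed to [compute_metric_fields()].
#' @param threshold,colour_noise_sd Delta E threshold and render noise used
#'   when `label_source = "image"`.
#' @return data.frame of class `sample_table` with columns `patient_id`,
#'   `region_type`, `region_no`, `node_id`, `wss`, `tawss`, `osi`, `rrt`,
#'   `wssd`, `pressure`; attribute `patient_max` holds each patient's
#'   whole-model maximum per metric (parent vessel included), attribute
#'   `transform` the per-metric transform tags (all `"raw"`).
#' @export
build_sample_table <- function(cohort, k = 10L, n_per_region = 2L,
                               margin_mm = 1.0,
                               label_source = c("truth", "image"),
                               wssd_mode = "time_averaged_field",
                               threshold = 10, colour_noise_sd = 2.5) {
  label_source <- match.arg(label_source)
  metric_names <- c("wss", "tawss", "osi", "rrt", "wssd", "pressure")
  rows <- vector("list", length(cohort))
  maxima <- matrix(NA_real_, length(cohort), length(metric_names),
                   dimnames = list(NULL, metric_names))
  for (i in seq_along(cohort)) {
    pat <- cohort[[i]]
    pid <- sprintf("P%02d", i)
    fields <- compute_metric_fields(pat$series, pat$mesh, wssd_mode = wssd_mode)
    labels <- if (label_source == "truth") {
      node_labels(pat$mesh, pat$truth$thin_nodes)
    } else {
      rz <- render_intraop_image(pat$mesh, pat$truth$thin_nodes,
                                 colour_noise_sd = colour_noise_sd,
                                 seed = derive_seed(attr(cohort, "config")$seed, i, stream = 7L))
      seg <- segment_thin_regions(rz$image, reference_pixels = seed_reference_pixels(rz),
                                  threshold = threshold)
      project_mask_to_mesh(seg, rz$camera, pat$mesh)
    }
    centres <- select_centre_points(labels, pat$mesh, n_per_region = n_per_region,
                                    margin_mm = margin_mm, patient_id = pid)
    vals <- sapply(fields, function(f) f$values)
    maxima[i, ] <- apply(vals, 2, max, na.rm = TRUE)
    pt_rows <- lapply(seq_len(nrow(centres)), function(j) {
      nodes <- extract_patch(pat$mesh, centres$node[j], k = k)
      v <- vals[nodes, , drop = FALSE]
      if (anyNA(v))
        stop(pid, ": undefined metric value at node(s) ",
             paste(nodes[rowSums(is.na(v)) > 0], collapse = ", "))
      data.frame(patient_id = pid,
                 region_type = as.character(centres$region_type[j]),
                 region_no = centres$region_no[j],
                 node_id = nodes, v)
    })
    rows[[i]] <- do.call(rbind, pt_rows)
  }
  tab <- do.call(rbind, rows)
  tab$patient_id <- factor(tab$patient_id)
  tab$region_type <- factor(tab$region_type, levels = c("normal", "thin"))
  tab <- tab[order(tab$patient_id, tab$region_no, tab$node_id), ]
  rownames(tab) <- NULL
  rownames(maxima) <- levels(tab$patient_id)
  attr(tab, "patient_max") <- maxima
  attr(tab, "transform") <- stats::setNames(rep("raw", length(metric_names)),
                                            metric_names)
  class(tab) <- c("sample_table", "data.frame")
  tab
}

#' Reference pixels for segmenting a rendered image
#'
#' Picks a small block of pixels at the centroid of the ground-truth mask —
#' the analogue of the clinician clicking a clearly red reference region.
#' @keywords internal
seed_reference_pixels <- function(render, block = 2L) {
  w <- which(render$mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("rendered thin mask is empty; cannot pick a reference region")
  ctr <- w[which.min(rowSums(sweep(w, 2, colMeans(w))^2)), ]
  rows <- pmax(1L, ctr[1] - block):pmin(nrow(render$mask), ctr[1] + block)
  cols <- pmax(1L, ctr[2] - block):pmin(ncol(render$mask), ctr[2] + block)
  sel <- as.matrix(expand.grid(rows, cols))
  keep <- render$mask[sel]
  sel <- sel[keep, , drop = FALSE]
  sel[, 1] + (sel[, 2] - 1L) * nrow(render$mask)
}

#' Write / read a sample table as CSV
#'
#' The per-patient maxima and transform tags ride along in a JSON sidecar
#' (`<path>.meta.json`) so a round-tripped table can still be normalised.
#' @param table a `sample_table`.
#' @param path CSV path.
#' @export
write_sample_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- list(patient_max = as.data.frame(attr(table, "patient_max")),
               transform = as.list(attr(table, "transform")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.csv(path)
  tab$patient_id <- factor(tab$patient_id)
  tab$region_type <- factor(tab$region_type, levels = c("normal", "thin"))
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pm <- as.matrix(meta$patient_max)
    rownames(pm) <- levels(tab$patient_id)
    attr(tab, "patient_max") <- pm
    attr(tab, "transform") <- unlist(meta$transform)
  }
  class(tab) <- c("sample_table", "data.frame")
  tab
}
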