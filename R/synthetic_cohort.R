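# Synthetic cohort generator: pulsatile tangential wall-shear fields and
# pressure on aneurysm meshes, with a known thin-patch effect and nested
# (patient / region-within-patient) random structure, so the downstream
# pipeline can be validated by parameter recovery.

#' Cohort configuration for the synthetic generator
#'
#' Defaults define the study conditions emulated by the generator: 16
#' patients, a two-harmonic pulsatile waveform over one cardiac cycle of
#' duration `cycle_T` seconds sampled at `n_timesteps` instants, a baseline
#' outlet-like pressure of 80 mmHg with a pulsatile component, and two
#' geodesic thin patches per dome in which the shear magnitude is multiplied
#' by `thin_wss_multiplier`, the shear direction is blended towards a
#' radially expanding (positively divergent) pattern with weight
#' `thin_divergence_weight`, and pressure is raised by
#' `thin_pressure_offset_pa` pascals.
#'
#' Random structure: a patient-level log-normal intercept (sd `patient_sd`),
#' per-patch log intercepts and a smooth patch-scale random field (sd
#' `region_sd`), and per-node log-normal noise (sd `noise_sd`), all on the
#' magnitude scale. The oscillatory content is a zero-mean cross-flow
#' component of relative amplitude `cross_frac`; because the thin-patch
#' multiplier scales the whole shear vector, OSI carries no injected
#' thin-region effect.
#'
#' @param n_patients number of patients (>= 1).
#' @param mean_wss_pa cycle-mean wall shear magnitude (Pa).
#' @param harmonics two relative harmonic amplitudes of the waveform.
#' @param cycle_T cardiac cycle duration (s).
#' @param n_timesteps number of time samples over `[0, cycle_T]` (>= 8).
#' @param systole_frac waveform peak location as a fraction of the cycle.
#' @param cross_frac relative amplitude of the zero-mean oscillatory
#'   cross-flow component (0 gives perfectly unidirectional shear and hence
#'   zero OSI; the default 0.5 yields OSI values on the few-percent scale
#'   typical of aneurysm domes).
#' @param thin_wss_multiplier multiplicative thin-patch shear elevation.
#' @param thin_divergence_weight blend weight (0..1) towards the radially
#'   expanding direction field inside thin patches.
#' @param thin_pressure_offset_pa additive thin-patch pressure offset (Pa).
#' @param pressure_baseline_mmhg baseline pressure (mmHg; 80 mmHg =
#'   10665.76 Pa).
#' @param pressure_pulse_pa amplitude of the pulsatile pressure component (Pa).
#' @param patient_sd,region_sd,noise_sd standard deviations of the nested
#'   random intercepts and residual node noise (log scale); all >= 0.
#' @param n_patches number of thin patches per dome.
#' @param patch_radius_mm geodesic radius of each thin patch (mm).
#' @param patch_polar_angle polar angle (radians from the dome apex) at which
#'   patch centres are placed; kept small enough that default patches are
#'   fully visible from the overhead rendering camera.
#' @param mesh_resolution preset name or list, see [generate_aneurysm_mesh()].
#' @param dome_radius_mm,vessel_radius_mm,vessel_length_mm mesh geometry (mm).
#' @param seed master integer seed; every patient is regenerable in isolation
#'   from documented sub-seeds derived from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 16L,
                          mean_wss_pa = 8,
                          harmonics = c(0.9, 0.35),
                          cycle_T = 1.0,
                          n_timesteps = 64L,
                          systole_frac = 0.15,
                          cross_frac = 0.5,
                          thin_wss_multiplier = 1.35,
                          thin_divergence_weight = 1.0,
                          thin_pressure_offset_pa = 250,
                          pressure_baseline_mmhg = 80,
                          pressure_pulse_pa = 2666,
                          patient_sd = 0.08,
                          region_sd = 0.10,
                          noise_sd = 0.12,
                          n_patches = 2L,
                          patch_radius_mm = 1.6,
                          patch_polar_angle = 0.7,
                          mesh_resolution = "medium",
                          dome_radius_mm = 2.5,
                          vessel_radius_mm = 1.5,
                          vessel_length_mm = 8,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), mean_wss_pa = mean_wss_pa,
              harmonics = harmonics, cycle_T = cycle_T,
              n_timesteps = as.integer(n_timesteps), systole_frac = systole_frac,
              cross_frac = cross_frac, thin_wss_multiplier = thin_wss_multiplier,
              thin_divergence_weight = thin_divergence_weight,
              thin_pressure_offset_pa = thin_pressure_offset_pa,
              pressure_baseline_mmhg = pressure_baseline_mmhg,
              pressure_pulse_pa = pressure_pulse_pa,
              patient_sd = patient_sd, region_sd = region_sd, noise_sd = noise_sd,
              n_patches = as.integer(n_patches), patch_radius_mm = patch_radius_mm,
              patch_polar_angle = patch_polar_angle,
              mesh_resolution = mesh_resolution,
              dome_radius_mm = dome_radius_mm, vessel_radius_mm = vessel_radius_mm,
              vessel_length_mm = vessel_length_mm, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @keywords internal
validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$n_timesteps < 8L) stop("n_timesteps must be >= 8")
  if (any(c(cfg$patient_sd, cfg$region_sd, cfg$noise_sd) < 0))
    stop("random-effect standard deviations must be >= 0")
  if (cfg$cycle_T <= 0) stop("cycle_T must be positive")
  if (cfg$thin_divergence_weight < 0 || cfg$thin_divergence_weight > 1)
    stop("thin_divergence_weight must lie in [0, 1]")
  invisible(TRUE)
}

#' Pulsatile waveform shape (dimensionless, unit mean)
#' @keywords internal
waveform_shape <- function(t, cfg) {
  ph <- 2 * pi * (t - cfg$systole_frac * cfg$cycle_T) / cfg$cycle_T
  1 + cfg$harmonics[1] * cos(ph) + cfg$harmonics[2] * cos(2 * ph)
}

#' Place thin-patch seed nodes on the dome
#'
#' Seeds sit on the ring of polar angle `patch_polar_angle` from the apex,
#' at a seeded random azimuth and (for two or more patches) evenly spaced
#' azimuths, so patches are disjoint and fully front-facing from the default
#' overhead camera.
#' @keywords internal
thin_patch_seeds <- function(mesh, cfg, seed) {
  set.seed(derive_seed(seed, 2L, stream = 23L))
  theta0 <- stats::runif(1, 0, 2 * pi)
  R <- cfg$dome_radius_mm
  h <- sqrt(R^2 - cfg$vessel_radius_mm^2)
  phi <- cfg$patch_polar_angle
  dome <- which(mesh$region == "dome")
  seeds <- integer(cfg$n_patches)
  for (p in seq_len(cfg$n_patches)) {
    th <- theta0 + (p - 1) * 2 * pi / cfg$n_patches
    target <- c(R * sin(phi) * cos(th), R * sin(phi) * sin(th), h + R * cos(phi))
    d2 <- rowSums(sweep(mesh$coords[dome, , drop = FALSE], 2, target)^2)
    seeds[p] <- dome[which.min(d2)]
  }
  seeds
}

#' Generate a pulsatile wall-shear/pressure series for one patient
#'
#' Produces per-node tangential WSS vectors (Pa) and pressure (Pa) on the
#' time grid `seq(0, cycle_T, length.out = n_timesteps)`, together with the
#' ground truth that was injected (thin-patch node set, multipliers, random
#' intercept draws). Every shear vector is orthogonal to its node normal by
#' construction. Reproducible: the same `(config, patient_index, seed)`
#' always yields bitwise-identical arrays.
#'
#' @param mesh an `aneurysm_mesh`.
#' @param config a `cohort_config`.
#' @param patient_index 1-based patient number (selects the per-patient
#'   sub-seed).
#' @param seed base seed; defaults to `config$seed`.
#' @return list with elements
#'   \describe{
#'     \item{series}{class `wss_series`: `times` (s), `cycle_T`,
#'       `wss` (nodes x times x 3 array, Pa), `pressure` (nodes x times, Pa)}
#'     \item{truth}{class `ground_truth`: thin node set, patch seeds and the
#'       injected effect sizes and random draws}
#'   }
#' @export
generate_wss_series <- function(mesh, config, patient_index = 1L,
                                seed = config$seed) {
  validate_cohort_config(config)
  n <- nrow(mesh$coords)
  times <- seq(0, config$cycle_T, length.out = config$n_timesteps)
  shape <- waveform_shape(times, config)
  stopifnot(all(shape > 0))

  pseed <- derive_seed(seed, patient_index, stream = 1L)
  seeds <- thin_patch_seeds(mesh, config, pseed)
  gd <- t(igraph::distances(mesh_graph(mesh), v = seeds,
                            to = igraph::V(mesh_graph(mesh))))
  nearest_patch <- max.col(-gd, ties.method = "first")
  rho <- gd[cbind(seq_len(n), nearest_patch)]
  thin <- which(rho <= config$patch_radius_mm & mesh$region == "dome")

  set.seed(derive_seed(pseed, 3L, stream = 5L))
  u_patient <- stats::rnorm(1, 0, config$patient_sd)
  v_patch <- stats::rnorm(length(seeds), 0, config$region_sd)
  # smooth patch-scale random field: Gaussian bumps on the surface
  n_bumps <- 8L
  bump_ctr <- mesh$coords[sample(which(mesh$region == "dome"), n_bumps), , drop = FALSE]
  bump_amp <- stats::rnorm(n_bumps, 0, config$region_sd)
  ell <- 1.2
  bump_field <- numeric(n)
  for (b in seq_len(n_bumps)) {
    d2 <- rowSums(sweep(mesh$coords, 2, bump_ctr[b, ])^2)
    bump_field <- bump_field + bump_amp[b] * exp(-d2 / (2 * ell^2))
  }
  node_noise <- stats::rnorm(n, 0, config$noise_sd)
  cf_patient <- stats::rnorm(1, 0, config$patient_sd)
  cf_noise <- stats::rnorm(n, 0, config$noise_sd)
  gp_patient <- stats::rnorm(1, 0, config$patient_sd)
  g_bump_amp <- stats::rnorm(n_bumps, 0, config$region_sd)
  g_noise <- stats::rnorm(n, 0, config$noise_sd)

  log_m <- u_patient + bump_field + node_noise
  log_m[thin] <- log_m[thin] + v_patch[nearest_patch[thin]] +
    log(config$thin_wss_multiplier)
  M <- config$mean_wss_pa * exp(log_m)

  # base direction: unit azimuthal swirl about the vessel axis (divergence-free
  # on the analytic surface), blended towards a radially expanding pattern
  # inside thin patches so the divergence has known positive sign there
  nrm <- mesh$normals
  zhat <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  e0 <- cross3(zhat, nrm)
  weak <- row_norms(e0) < 1e-6
  if (any(weak)) {           # apex-like nodes where the normal is axial
    fb <- cbind(1, 0, 0) [rep(1, sum(weak)), , drop = FALSE]
    fb <- fb - nrm[weak, , drop = FALSE] * rowSums(fb * nrm[weak, , drop = FALSE])
    e0[weak, ] <- fb
  }
  e0 <- normalize_rows(e0)
  e <- e0
  if (length(thin) > 0 && config$thin_divergence_weight > 0) {
    ctr <- mesh$coords[seeds[nearest_patch[thin]], , drop = FALSE]
    off <- mesh$coords[thin, , drop = FALSE] - ctr
    off <- off - nrm[thin, , drop = FALSE] * rowSums(off * nrm[thin, , drop = FALSE])
    ok <- row_norms(off) > 1e-9
    u_rad <- normalize_rows(off)
    lam <- config$thin_divergence_weight *
      pmax(0, 1 - (rho[thin] / config$patch_radius_mm)^4)
    blend <- (1 - lam) * e0[thin, , drop = FALSE] + lam * u_rad
    keep <- ok & row_norms(blend) > 1e-9
    e[thin[keep], ] <- normalize_rows(blend[keep, , drop = FALSE])
  }
  # re-orthogonalise against the node normal and renormalise (guards against
  # accumulation of rounding in the blend)
  e <- e - nrm * rowSums(e * nrm)
  e <- normalize_rows(e)
  cvec <- normalize_rows(cross3(nrm, e))

  cf <- config$cross_frac * exp(cf_patient + cf_noise)
  osc <- sin(2 * pi * times / config$cycle_T)

  wss <- array(0, dim = c(n, length(times), 3))
  for (ti in seq_along(times)) {
    coef_e <- M * shape[ti]
    coef_c <- M * cf * osc[ti]
    wss[, ti, ] <- e * coef_e + cvec * coef_c
  }

  p0 <- config$pressure_baseline_mmhg * 133.322
  g <- exp(gp_patient + {
    bf <- numeric(n)
    for (b in seq_len(n_bumps)) {
      d2 <- rowSums(sweep(mesh$coords, 2, bump_ctr[b, ])^2)
      bf <- bf + g_bump_amp[b] * exp(-d2 / (2 * ell^2))
    }
    bf
  } + g_noise)
  ph <- 2 * pi * (times - config$systole_frac * config$cycle_T) / config$cycle_T
  pressure <- outer(g, cos(ph)) * config$pressure_pulse_pa + p0
  if (length(thin) > 0)
    pressure[thin, ] <- pressure[thin, ] + config$thin_pressure_offset_pa

  series <- structure(list(times = times, cycle_T = config$cycle_T,
                           wss = wss, pressure = pressure),
                      class = "wss_series")
  truth <- structure(list(
    patient_index = patient_index,
    thin_nodes = thin,
    patch_seeds = seeds,
    patch_of_thin_node = nearest_patch[thin],
    thin_wss_multiplier = config$thin_wss_multiplier,
    thin_divergence_weight = config$thin_divergence_weight,
    thin_pressure_offset_pa = config$thin_pressure_offset_pa,
    patient_intercept = u_patient,
    patch_intercepts = v_patch,
    pressure_patient_intercept = gp_patient,
    systolic_time = times[which.max(shape)]),
    class = "ground_truth")
  list(series = series, truth = truth)
}

#' Validate a WSS field series against its mesh
#' @param series a `wss_series`.
#' @param mesh the `aneurysm_mesh` it was generated on.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_series <- function(series, mesh) {
  n <- nrow(mesh$coords)
  if (dim(series$wss)[1] != n || nrow(series$pressure) != n)
    stop("field array dimensions do not match the mesh node count")
  if (series$times[1] != 0 ||
      abs(series$times[length(series$times)] - series$cycle_T) > 1e-12)
    stop("times must span [0, cycle_T]")
  if (!all(is.finite(series$wss)) || !all(is.finite(series$pressure)))
    stop("non-finite field values")
  invisible(TRUE)
}

#' Simulate a full synthetic cohort
#'
#' Generates one mesh and one field series per patient. Patient meshes share
#' the configured geometry but differ in their seeded node jitter; every
#' patient can be regenerated in isolation from the master seed.
#'
#' @param config a `cohort_config`.
#' @return list of class `synthetic_cohort`: one element per patient, each
#'   with `mesh`, `series`, `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  patients <- lapply(seq_len(config$n_patients), function(i) {
    mesh <- generate_aneurysm_mesh(
      dome_radius_mm = config$dome_radius_mm,
      vessel_radius_mm = config$vessel_radius_mm,
      resolution = config$mesh_resolution,
      vessel_length_mm = config$vessel_length_mm,
      seed = derive_seed(config$seed, i, stream = 2L))
    gen <- generate_wss_series(mesh, config, patient_index = i)
    list(mesh = mesh, series = gen$series, truth = gen$truth)
  })
  structure(patients, class = "synthetic_cohort", config = config)
}

#' Simulate a sample table directly from the nested mixed-model truth
#'
#' Draws `Y = beta0 + beta1 * thin + u_patient + v_region + noise` with the
#' sampling design of the regional analysis (`n_per_region` centres per
#' region type per patient, `k` rows per centre), bypassing the field
#' generator. This is the reference generator for parameter-recovery and
#' type-I-error simulations of the mixed-model stage.
#'
#' @param n_patients number of patients.
#' @param beta0 intercept (normal-region mean).
#' @param beta1 fixed thin-minus-normal effect.
#' @param patient_sd,region_sd,noise_sd standard deviations of the patient
#'   intercept, the region-within-patient intercept, and the residual.
#' @param n_per_region centres per region type per patient.
#' @param k rows (nodes) per centre.
#' @param seed integer seed.
#' @return a sample table (`data.frame`) with columns `patient_id`,
#'   `region_type`, `region_no`, `node_id`, `y`, plus attribute `truth`.
#' @export
simulate_lmm_table <- function(n_patients = 16L, beta0 = 0.14, beta1 = 0.03,
                               patient_sd = 0.02, region_sd = 0.05,
                               noise_sd = 0.07, n_per_region = 2L, k = 10L,
                               seed = 1L) {
  set.seed(derive_seed(seed, 1L, stream = 31L))
  n_regions <- 2L * n_per_region
  rows <- n_patients * n_regions * k
  patient <- rep(seq_len(n_patients), each = n_regions * k)
  region_no <- rep(rep(seq_len(n_regions), each = k), times = n_patients)
  thin <- region_no <= n_per_region
  u <- stats::rnorm(n_patients, 0, patient_sd)
  v <- stats::rnorm(n_patients * n_regions, 0, region_sd)
  region_key <- (patient - 1L) * n_regions + region_no
  y <- beta0 + beta1 * thin + u[patient] + v[region_key] +
    stats::rnorm(rows, 0, noise_sd)
  tab <- data.frame(
    patient_id = factor(sprintf("P%02d", patient)),
    region_type = factor(ifelse(thin, "thin", "normal"),
                         levels = c("normal", "thin")),
    region_no = as.integer(region_no),
    node_id = rep(seq_len(k), times = n_patients * n_regions),
    y = y)
  attr(tab, "truth") <- list(beta0 = beta0, beta1 = beta1,
                             patient_sd = patient_sd, region_sd = region_sd,
                             noise_sd = noise_sd)
  attr(tab, "transform") <- c(y = "raw")
  tab
}
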