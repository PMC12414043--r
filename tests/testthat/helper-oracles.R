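# Independent reference implementations used only as test oracles.
# They deliberately share no code with the package internals.

# sRGB (8-bit) -> CIELAB under D65, written out step by step from the
# published definition of the sRGB transfer curve and the Lab functions.
oracle_srgb_to_lab <- function(rgb255) {
  v <- rgb255 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  white <- c(0.95047, 1.0, 1.08883)   # D65
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / white[1]); fy <- f(xyz[2] / white[2]); fz <- f(xyz[3] / white[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Scalar, step-by-step CIEDE2000 following the published formula layout
# (independent of the vectorised package implementation).
oracle_ciede2000 <- function(lab1, lab2) {
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]
  rad <- pi / 180
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cb <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cb^7 / (Cb^7 + 25^7)))
  a1p <- a1 * (1 + G); a2p <- a2 * (1 + G)
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- if (C1p == 0) 0 else { h <- atan2(b1, a1p) / rad; if (h < 0) h + 360 else h }
  h2p <- if (C2p == 0) 0 else { h <- atan2(b2, a2p) / rad; if (h < 0) h + 360 else h }
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    d <- h2p - h1p
    if (d > 180) d - 360 else if (d < -180) d + 360 else d
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * rad / 2)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    if (abs(h1p - h2p) <= 180) (h1p + h2p) / 2
    else if (h1p + h2p < 360) (h1p + h2p) / 2 + 180
    else (h1p + h2p) / 2 - 180
  }
  Tt <- 1 - 0.17 * cos((hbp - 30) * rad) + 0.24 * cos(2 * hbp * rad) +
    0.32 * cos((3 * hbp + 6) * rad) - 0.20 * cos((4 * hbp - 63) * rad)
  dth <- 30 * exp(-((hbp - 275) / 25)^2)
  Rc <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  Sl <- 1 + (0.015 * (Lbp - 50)^2) / sqrt(20 + (Lbp - 50)^2)
  Sc <- 1 + 0.045 * Cbp
  Sh <- 1 + 0.015 * Cbp * Tt
  Rt <- -sin(2 * dth * rad) * Rc
  sqrt((dLp / Sl)^2 + (dCp / Sc)^2 + (dHp / Sh)^2 +
         Rt * (dCp / Sc) * (dHp / Sh))
}

# Direct elementwise evaluation of the OSI definition with explicit loops.
oracle_osi_node <- function(w_node, times) {
  n <- length(times)
  trap <- function(f) sum(diff(times) * (f[-1] + f[-n]) / 2)
  ints <- sapply(1:3, function(c) trap(w_node[, c]))
  mag <- trap(sqrt(rowSums(w_node^2)))
  if (mag == 0) return(0)
  0.5 * (1 - sqrt(sum(ints^2)) / mag)
}

# Brute-force 1-ring weighted least-squares divergence: one explicit
# normal-equation solve per node via solve().
oracle_wssd <- function(field, mesh) {
  n <- nrow(mesh$coords)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- mesh$adjacency[[i]]
    if (length(nb) < 3L) next
    D <- sweep(mesh$coords[nb, , drop = FALSE], 2, mesh$coords[i, ])
    w <- 1 / sqrt(rowSums(D^2))
    A <- t(D * w) %*% D
    if (abs(det(A)) <= 1e-10 * max(sum(diag(A)) / 3, 1e-300)^3) next
    div <- 0
    for (comp in 1:3) {
      b <- t(D * w) %*% (field[nb, comp] - field[i, comp])
      g <- solve(A, b)
      div <- div + g[comp]
    }
    out[i] <- div
  }
  out
}

# Random tangential field series on a mesh (seeded), for property tests.
random_series <- function(mesh, n_times = 12L, seed = 1L, tangential = FALSE) {
  set.seed(seed)
  n <- nrow(mesh$coords)
  times <- seq(0, 1, length.out = n_times)
  w <- array(rnorm(n * n_times * 3), dim = c(n, n_times, 3))
  if (tangential) {
    for (ti in seq_len(n_times)) {
      v <- w[, ti, ]
      v <- v - mesh$normals * rowSums(v * mesh$normals)
      w[, ti, ] <- v
    }
  }
  structure(list(times = times, cycle_T = 1,
                 wss = w, pressure = matrix(0, n, n_times)),
            class = "wss_series")
}

# Small series built from an explicit array, for closed-form cases.
series_from_array <- function(w, times = seq(0, 1, length.out = dim(w)[2]),
                              cycle_T = max(times), pressure = NULL) {
  if (is.null(pressure)) pressure <- matrix(0, dim(w)[1], dim(w)[2])
  structure(list(times = times, cycle_T = cycle_T, wss = w, pressure = pressure),
            class = "wss_series")
}

# 3D rotation matrix from an axis and angle.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Shared small mesh (computed once per test run).
test_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_aneurysm_mesh(resolution = "coarse", seed = 7L)
    cache
  }
})
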