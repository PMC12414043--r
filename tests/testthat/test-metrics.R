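test_that("TaWSS reproduces constant, zero and sinusoidal closed forms", {
  n <- 5L; nt <- 513L
  times <- seq(0, 1, length.out = nt)
  wconst <- array(0, dim = c(n, nt, 3)); wconst[, , 1] <- 3; wconst[, , 2] <- 4
  expect_equal(tawss(series_from_array(wconst, times))$values, rep(5, n),
               tolerance = 1e-12)
  expect_equal(tawss(series_from_array(array(0, dim = c(n, nt, 3)), times))$values,
               rep(0, n))
  # W(t) = (A sin(2 pi t / T), 0, 0): time-averaged |W| -> 2A/pi
  A <- 2.7
  wsin <- array(0, dim = c(1, nt, 3))
  wsin[1, , 1] <- A * sin(2 * pi * times)
  got <- tawss(series_from_array(wsin, times))$values
  # fine-quadrature oracle
  tf <- seq(0, 1, length.out = 1e5 + 1)
  ref <- sum(diff(tf) * (abs(A * sin(2 * pi * tf))[-1] +
                         abs(A * sin(2 * pi * tf))[-length(tf)]) / 2)
  expect_equal(got, ref, tolerance = 1e-4)
  expect_equal(got, 2 * A / pi, tolerance = 1e-3)
  expect_error(tawss(series_from_array(wsin, times, cycle_T = 0)), "positive|increasing")
})

test_that("OSI hits its closed forms and matches brute-force evaluation", {
  nt <- 65L
  times <- seq(0, 1, length.out = nt)
  # unidirectional: fixed direction, positive magnitude
  w <- array(0, dim = c(3, nt, 3))
  for (i in 1:3) w[i, , 1] <- 1 + 0.5 * cos(2 * pi * times)
  expect_equal(osi(series_from_array(w, times))$values, rep(0, 3), tolerance = 1e-12)
  # zero-mean sinusoid over a full cycle: OSI = 0.5
  ws <- array(0, dim = c(2, nt, 3))
  ws[, , 2] <- matrix(rep(sin(2 * pi * times), each = 2), 2)
  expect_equal(osi(series_from_array(ws, times))$values, rep(0.5, 2), tolerance = 1e-12)
  # random series vs direct evaluation of the definition
  m <- test_mesh()
  s <- random_series(m, n_times = 17L, seed = 21L)
  got <- osi(s)$values
  ref <- vapply(seq_len(nrow(m$coords)), function(i) oracle_osi_node(s$wss[i, , ], s$times),
                numeric(1))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("OSI stays within [0, 0.5] on random fields", {
  set.seed(13)
  for (rep in 1:40) {
    nt <- sample(8:24, 1)
    n <- sample(5:40, 1)
    w <- array(rnorm(n * nt * 3, sd = runif(1, 0.1, 10)), dim = c(n, nt, 3))
    o <- osi(series_from_array(w))$values
    expect_true(all(o >= 0 & o <= 0.5))
  }
  # zero field returns 0 by convention
  expect_equal(osi(series_from_array(array(0, dim = c(4, 9, 3))))$values, rep(0, 4))
})

test_that("RRT is the guarded reciprocal and satisfies the round-trip identity", {
  ta <- structure(list(name = "TaWSS", values = c(4, 10, 2), units = "Pa"),
                  class = "metric_field")
  os <- structure(list(name = "OSI", values = c(0, 0.25, 0.5), units = ""),
                  class = "metric_field")
  r <- rrt(ta, os)
  expect_equal(r$values[1], 0.25)
  expect_equal(r$values[2], 0.2)
  expect_true(is.na(r$values[3]))   # OSI = 0.5: undefined, not clipped
  os_bad <- structure(list(name = "OSI", values = c(0, 0.25), units = ""),
                      class = "metric_field")
  expect_error(rrt(ta, os_bad), "mismatch")
  # identity RRT * TaWSS * (1 - 2 OSI) = 1 wherever defined, on random fields
  m <- test_mesh()
  s <- random_series(m, n_times = 12L, seed = 31L)
  taf <- tawss(s); osf <- osi(s); rf <- rrt(taf, osf)
  ok <- !is.na(rf$values)
  expect_gt(mean(ok), 0.9)
  expect_equal(rf$values[ok] * taf$values[ok] * (1 - 2 * osf$values[ok]),
               rep(1, sum(ok)), tolerance = 1e-10)
})

test_that("TaWSS is bracketed by the mean-vector and peak magnitudes", {
  m <- test_mesh()
  s <- random_series(m, n_times = 15L, seed = 8L)
  ta <- tawss(s)$values
  mag <- sqrt(s$wss[, , 1]^2 + s$wss[, , 2]^2 + s$wss[, , 3]^2)
  peak <- apply(mag, 1, max)
  w <- diff(s$times); wts <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  meanvec <- sqrt((s$wss[, , 1] %*% wts)^2 + (s$wss[, , 2] %*% wts)^2 +
                  (s$wss[, , 3] %*% wts)^2) / s$cycle_T
  expect_true(all(ta <= peak + 1e-12))
  expect_true(all(ta >= meanvec - 1e-12))
})

test_that("WSSD is exact on linear fields and zero on constant fields", {
  m <- test_mesh()
  const <- matrix(rep(c(1.5, -2, 0.7), each = nrow(m$coords)), ncol = 3)
  d0 <- wssd(const, m)$values
  expect_equal(max(abs(d0), na.rm = TRUE), 0, tolerance = 1e-10)
  G <- matrix(c(2, 0.5, -1, 0, 3, 0.2, 1, -0.4, 0.5), 3, 3, byrow = TRUE)
  lin <- m$coords %*% t(G)
  dv <- wssd(lin, m)$values
  interior <- which(!is.na(dv))
  expect_gt(length(interior), 0.9 * nrow(m$coords))
  expect_lt(max(abs(dv[interior] - sum(diag(G)))) / abs(sum(diag(G))), 1e-6)
})

test_that("WSSD equals the brute-force normal-equation solve", {
  m <- test_mesh()
  set.seed(17)
  field <- matrix(rnorm(nrow(m$coords) * 3), ncol = 3)
  got <- wssd(field, m)$values
  ref <- oracle_wssd(field, m)
  expect_identical(is.na(got), is.na(ref))
  ok <- !is.na(got)
  expect_equal(got[ok], ref[ok], tolerance = 1e-10)
})

test_that("surface-mode WSSD converges to the analytic surface divergence", {
  # tangential meridional field on the spherical dome: W = sin(theta) e_theta,
  # whose surface divergence is 2 cos(theta) / R
  err_for <- function(preset) {
    m <- generate_aneurysm_mesh(resolution = preset, seed = 5L, jitter = 0)
    R <- 2.5; h <- 2
    rel <- sweep(m$coords, 2, c(0, 0, h))
    th <- acos(pmin(pmax(rel[, 3] / sqrt(rowSums(rel^2)), -1), 1))
    ph <- atan2(rel[, 2], rel[, 1])
    e_th <- cbind(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
    dv <- wssd(e_th * sin(th), m, divergence = "surface")$values
    truth <- 2 * cos(th) / R
    keep <- which(m$region == "dome" & th > 0.35 & th < 1.4 & !is.na(dv))
    stats::median(abs(dv[keep] - truth[keep]))
  }
  e_coarse <- err_for("coarse")
  e_fine <- err_for("fine")
  # node spacing halves coarse -> fine; observed order >= 1 means >= 2x drop
  expect_lt(e_fine, e_coarse / 2)
})

test_that("ambient WSSD's normal-direction bias vanishes on linear fields only", {
  # the ambient trace on a curved surface carries a curvature-coupled error
  # for fields with nonzero Hessian; the surface mode removes it
  m <- generate_aneurysm_mesh(resolution = "coarse", seed = 5L, jitter = 0)
  f <- m$coords^2
  amb <- wssd(f, m, divergence = "ambient")$values
  srf <- wssd(f, m, divergence = "surface")$values
  keep <- which(!is.na(amb) & m$region == "dome" & m$coords[, 3] > 2)
  expect_gt(stats::median(abs(amb[keep] - srf[keep])), 0.1)  # modes genuinely differ
  lin <- m$coords %*% matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 3), 3)
  expect_lt(max(abs(wssd(lin, m)$values - 6), na.rm = TRUE), 1e-8)
})

test_that("all metrics are invariant under rigid rotation of mesh and field", {
  m <- test_mesh()
  cfg <- cohort_config(n_patients = 1L, mesh_resolution = "coarse")
  s <- generate_wss_series(m, cfg, patient_index = 1L)$series
  R <- rotation_matrix(c(1, 2, 0.5), 0.83)
  m_rot <- m
  m_rot$coords <- m$coords %*% t(R)
  m_rot$normals <- m$normals %*% t(R)
  m_rot$graph <- NULL
  s_rot <- s
  for (ti in seq_along(s$times)) s_rot$wss[, ti, ] <- s$wss[, ti, ] %*% t(R)
  f1 <- compute_metric_fields(s, m)
  f2 <- compute_metric_fields(s_rot, m_rot)
  for (nm in names(f1)) {
    a <- f1[[nm]]$values; b <- f2[[nm]]$values
    expect_equal(a, b, tolerance = 1e-8, label = nm)
  }
})

test_that("systolic instant is the argmax of mesh-mean magnitude and is stable", {
  nt <- 33L
  times <- seq(0, 1, length.out = nt)
  w <- array(0, dim = c(4, nt, 3))
  w[, , 1] <- matrix(rep(2 + cos(2 * pi * (times - 0.25)), each = 4), 4)
  s <- series_from_array(w, times)
  expect_identical(systolic_index(s), which.max(2 + cos(2 * pi * (times - 0.25))))
  expect_equal(systolic_wss(s)$values, rep(max(2 + cos(2 * pi * (times - 0.25))), 4))
  # constant-magnitude field: systolic WSS equals that magnitude
  wc <- array(0, dim = c(3, nt, 3)); wc[, , 3] <- 7
  expect_equal(systolic_wss(series_from_array(wc, times))$values, rep(7, 3))
  # two patients, same seed: identical systolic index by determinism
  m <- test_mesh()
  cfg <- cohort_config(n_patients = 2L, mesh_resolution = "coarse")
  s1 <- generate_wss_series(m, cfg, patient_index = 1L)$series
  s2 <- generate_wss_series(m, cfg, patient_index = 2L)$series
  expect_identical(systolic_index(s1), systolic_index(s2))
})

test_that("pressure summaries honour the 80 mmHg baseline and waveform closed forms", {
  nt <- 64L
  times <- seq(0, 1, length.out = nt)
  n <- 6L
  w <- array(0, dim = c(n, nt, 3))
  w[, , 1] <- matrix(rep(1 + 0.5 * cos(2 * pi * times), each = n), n)
  # constant 80 mmHg
  p80 <- matrix(80 * 133.322, n, nt)
  s <- series_from_array(w, times, pressure = p80)
  expect_equal(pressure_summary(s)$values, rep(10665.76, n), tolerance = 1e-9)
  expect_equal(pressure_summary(s, "time_averaged")$values, rep(10665.76, n),
               tolerance = 1e-9)
  # zero-mean pulsatile component: time average returns the baseline exactly
  amp <- 1500
  pp <- p80 + amp * matrix(rep(cos(2 * pi * times), each = n), n)
  sp <- series_from_array(w, times, pressure = pp)
  expect_equal(pressure_summary(sp, "time_averaged")$values, rep(10665.76, n),
               tolerance = 1e-8)
  # systolic mode on a single-peak waveform: baseline + amplitude
  expect_equal(pressure_summary(sp, "systolic")$values, rep(10665.76 + amp, n),
               tolerance = 1e-9)
  s_no_p <- s; s_no_p$pressure <- NULL
  expect_error(pressure_summary(s_no_p), "no pressure")
})

test_that("two-cycle series are summarised from the second cycle only", {
  nt <- 41L
  t1 <- seq(0, 1, length.out = nt)
  t2 <- seq(0, 2, length.out = 2 * nt - 1)
  w1 <- array(0, dim = c(2, nt, 3))
  w1[, , 1] <- matrix(rep(2 + sin(2 * pi * t1), each = 2), 2)
  # first cycle deliberately corrupted; second cycle equals the single-cycle field
  w2 <- array(0, dim = c(2, 2 * nt - 1, 3))
  w2[, , 1] <- matrix(rep(c(10 * (2 + sin(2 * pi * t1[-nt])), 2 + sin(2 * pi * t1)),
                          each = 2), 2)
  s1 <- series_from_array(w1, t1, cycle_T = 1)
  s2 <- series_from_array(w2, t2, cycle_T = 1)
  expect_equal(tawss(s2)$values, tawss(s1)$values, tolerance = 1e-12)
  expect_equal(osi(s2)$values, osi(s1)$values, tolerance = 1e-12)
})
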