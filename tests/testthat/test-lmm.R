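# A small deterministic table with known per-patient maxima, used by the
# transform tests.
toy_table <- function() {
  tab <- data.frame(
    patient_id = factor(rep(c("P01", "P02"), each = 4)),
    region_type = factor(rep(c("normal", "thin"), 4), levels = c("normal", "thin")),
    region_no = rep(1:4, 2),
    node_id = 1:8,
    y = c(5, 5, 2, 2, 3, 3, 6, 6),
    osi = rep(0.1, 8))
  attr(tab, "patient_max") <- matrix(c(10, 6, 0.5, 0.5), 2, 2,
                                     dimnames = list(c("P01", "P02"), c("y", "osi")))
  attr(tab, "transform") <- c(y = "raw", osi = "raw")
  class(tab) <- c("sample_table", "data.frame")
  tab
}

test_that("transforms behave per contract: raw identity, per-patient scaling, guarded log", {
  tab <- toy_table()
  raw <- apply_transform(tab, "raw")
  expect_identical(raw$y, tab$y)
  norm <- apply_transform(tab, transform_spec("patient_max", except = c(osi = "raw")))
  # patient A max 10, value 5 -> 0.5, independent of patient B
  expect_equal(norm$y, c(0.5, 0.5, 0.2, 0.2, 0.5, 0.5, 1, 1))
  expect_identical(attr(norm, "transform")[["y"]], "patient_max")
  expect_identical(attr(norm, "transform")[["osi"]], "raw")
  # every sampled value at its patient max -> all ones
  at_max <- tab; at_max$y <- attr(tab, "patient_max")[as.character(tab$patient_id), "y"]
  expect_equal(apply_transform(at_max, "patient_max")$y, rep(1, 8))
  lg <- apply_transform(tab, transform_spec("log", except = c(osi = "raw")))
  expect_equal(lg$y, log(tab$y))
  neg <- tab; neg$y[1] <- -1
  expect_error(apply_transform(neg, "log"), "<= 0")
  zero_max <- tab; attr(zero_max, "patient_max")["P01", "y"] <- 0
  expect_error(apply_transform(zero_max, "patient_max"), "zero")
  expect_error(apply_transform(tab, transform_spec("log", except = c())), "OSI")
  double <- apply_transform(tab, "patient_max")
  expect_error(apply_transform(double, "patient_max"), "already transformed")
})

test_that("signed values are divided by the signed patient maximum", {
  tab <- toy_table()
  tab$y <- c(-5, 5, 2, -2, 3, 3, -6, 6)
  norm <- apply_transform(tab, "patient_max")
  expect_equal(norm$y,
               unname(tab$y / attr(tab, "patient_max")[as.character(tab$patient_id), "y"]))
  expect_true(any(norm$y < 0))
})

test_that("a zero-noise additive table is fitted exactly", {
  t0 <- simulate_lmm_table(patient_sd = 0, region_sd = 0, noise_sd = 0,
                           beta0 = 0.1, beta1 = 0.05, seed = 2L)
  f <- fit_lmm(t0, "y")
  expect_equal(f$beta1, 0.05, tolerance = 1e-6)
  expect_equal(f$beta0, 0.1, tolerance = 1e-6)
  expect_lt(max(f$var_patient, f$var_region, f$var_residual), 1e-8)
})

test_that("estimates respond correctly to shifts and label recoding", {
  tab <- simulate_lmm_table(seed = 6L)
  f <- fit_lmm(tab, "y")
  shifted <- tab; shifted$y <- shifted$y + 3
  fs <- fit_lmm(shifted, "y")
  expect_equal(fs$beta0, f$beta0 + 3, tolerance = 1e-6)
  expect_equal(fs$beta1, f$beta1, tolerance = 1e-8)
  flipped <- tab
  flipped$region_type <- factor(ifelse(tab$region_type == "thin", "normal", "thin"),
                                levels = c("normal", "thin"))
  ff <- fit_lmm(flipped, "y")
  expect_equal(ff$beta1, -f$beta1, tolerance = 1e-8)
  expect_true(f$ci[1] <= f$beta1 && f$beta1 <= f$ci[2])
  expect_gte(min(f$var_patient, f$var_region, f$var_residual), 0)
  expect_true(is.finite(f$aic))
})

test_that("model structures and precondition failures are enforced", {
  tab <- simulate_lmm_table(seed = 10L)
  f1 <- fit_lmm(tab, "y", model = "model1")
  f2 <- fit_lmm(tab, "y", model = "model2")
  expect_identical(f1$model, "model1")
  expect_identical(f2$model, "model2")
  one_pat <- tab[tab$patient_id == "P01", ]
  expect_error(fit_lmm(one_pat, "y"), "2 patients")
  thin_only <- tab[tab$region_type == "thin", ]
  expect_error(fit_lmm(thin_only, "y"), "region types")
  expect_error(fit_lmm(tab, "nope"), "not found")
})

test_that("AIC comparison demands equal rows, and a useless variance component never wins", {
  tab <- simulate_lmm_table(seed = 20L)
  f2 <- fit_lmm(tab, "y")
  f2b <- fit_lmm(tab, "y")
  cmp <- compare_models_aic(list(a = f2, b = f2b))
  expect_equal(cmp$delta_aic, c(0, 0), tolerance = 1e-10)
  short <- fit_lmm(tab[1:320, ], "y")
  expect_error(compare_models_aic(list(f2, short)), "differing row counts")
  # nested-model property on null data (no region-level variance): the richer
  # model's restricted likelihood is never below the patient-only fit, and the
  # extra useless component typically costs the full +2 AIC penalty. (The AIC
  # difference is chi-bar-square distributed, so single replicates can favour
  # the richer model; the guarantee is the likelihood ordering plus the
  # typical penalty, asserted over replicates.)
  aic_diff <- sapply(1:10, function(s) {
    null_tab <- simulate_lmm_table(region_sd = 0, seed = 120L + s)
    fit_full <- fit_lmm(null_tab, "y")
    fit_patient_only <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ region_type + (1 | patient_id), data = null_tab, REML = TRUE)))
    expect_gte(as.numeric(stats::logLik(fit_full$fit)),
               as.numeric(stats::logLik(fit_patient_only)) - 1e-6)
    fit_full$aic - stats::AIC(fit_patient_only)
  })
  expect_gte(stats::median(aic_diff), 0)
})

test_that("patient-maximum normalisation improves AIC on scale-heterogeneous data", {
  # patients whose metric scales differ by orders of magnitude (heavy right
  # skew pooled), the regime in which per-patient normalisation pays off
  set.seed(77)
  n_pat <- 12L
  scale_i <- exp(rnorm(n_pat, 0, 1.5))
  rows <- lapply(seq_len(n_pat), function(i) {
    v <- scale_i[i] * exp(rnorm(40, 0, 0.4))
    data.frame(patient_id = sprintf("P%02d", i),
               region_type = rep(c("thin", "normal"), each = 20),
               region_no = rep(1:4, each = 10), node_id = 1:40, y = v)
  })
  tab <- do.call(rbind, rows)
  tab$patient_id <- factor(tab$patient_id)
  tab$region_type <- factor(tab$region_type, levels = c("normal", "thin"))
  pm <- matrix(tapply(tab$y, tab$patient_id, max) * 1.1, ncol = 1,
               dimnames = list(levels(tab$patient_id), "y"))
  attr(tab, "patient_max") <- pm
  attr(tab, "transform") <- c(y = "raw")
  class(tab) <- c("sample_table", "data.frame")
  f_raw <- fit_lmm(tab, "y")
  f_norm <- fit_lmm(apply_transform(tab, "patient_max"), "y")
  expect_lt(f_norm$aic, f_raw$aic)
})

test_that("residual diagnostics emit consistent datasets and a normality summary", {
  tab <- simulate_lmm_table(seed = 30L)
  f <- fit_lmm(tab, "y")
  d <- residual_diagnostics(f)
  expect_identical(sum(d$histogram$count), f$n_obs)
  expect_identical(nrow(d$qq), f$n_obs)
  expect_identical(nrow(d$resid_fitted), f$n_obs)
  expect_identical(d$by_order$order, seq_len(f$n_obs))
  expect_lt(abs(sum(f$residuals)), 1e-8)
  # near-normal residuals: QQ hugs the identity line, Shapiro does not reject
  expect_lt(max(abs(d$qq$theoretical - d$qq$sample)), 0.6)
  expect_gt(cor(d$qq$theoretical, d$qq$sample), 0.99)
  expect_gt(d$shapiro_p, 1e-4)
})

test_that("effect summaries express coefficients as fractions of the patient maximum", {
  mk <- function(beta0, beta1, transform = "patient_max") {
    structure(list(beta0 = beta0, beta1 = beta1,
                   ci = beta1 + c(-1, 1) * 0.005, p_value = 1e-4,
                   metric = "wss", transform = transform),
              class = "aneuwall_lmm")
  }
  r <- summarize_effects(mk(0.140, 0.033))
  expect_equal(r$thin_mean, 0.173)
  expect_equal(r$pct_of_patient_max, 3.3)
  r2 <- summarize_effects(mk(0.908, 0.013))
  expect_equal(r2$thin_mean, 0.921)
  r0 <- summarize_effects(mk(0.5, 0))
  expect_equal(r0$thin_mean, r0$normal_mean)
  expect_equal(r0$pct_of_patient_max, 0)
  expect_error(summarize_effects(mk(0.1, 0.05, transform = "raw")), "patient_max")
})

test_that("permuting region-type labels within patients centres the effect on zero", {
  tab <- simulate_lmm_table(beta1 = 0, seed = 40L)
  set.seed(41)
  n_perm <- 50L
  betas <- numeric(n_perm)
  pvals <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    perm <- tab
    for (p in levels(tab$patient_id)) {
      idx <- tab$patient_id == p
      thin_regions <- sample(1:4, 2)
      perm$region_type[idx] <- factor(
        ifelse(tab$region_no[idx] %in% thin_regions, "thin", "normal"),
        levels = c("normal", "thin"))
    }
    f <- fit_lmm(perm, "y")
    betas[r] <- f$beta1
    pvals[r] <- f$p_value
  }
  expect_lt(abs(mean(betas)), 2 * sd(betas) / sqrt(n_perm) + 0.01)
  expect_lte(mean(pvals < 0.05), 0.15)   # nominal 5% with binomial slack
})

test_that("injected effects are recovered from the direct table generator", {
  truth <- 0.03
  n_rep <- 20L
  est <- numeric(n_rep); cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- simulate_lmm_table(beta1 = truth, seed = 100L + r)
    f <- fit_lmm(tab, "y")
    est[r] <- f$beta1
    cover[r] <- f$ci[1] <= truth && truth <= f$ci[2]
  }
  expect_lt(abs(mean(est) - truth), 0.01)
  expect_gte(sum(cover), 16L)
})
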