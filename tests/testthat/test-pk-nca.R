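mono_profile <- function(times = c(0.25, 0.5, 1, 2, 4, 7, 24), c0 = 100,
                         k = 0.5, route = "iv_bolus", lloq = 0, ...) {
  pk_profile(route = route, dose = 1, times = times,
             conc = c0 * exp(-k * times), lloq = lloq, ...)
}

test_that("BLQ censoring rules behave as documented", {
  p <- pk_profile(route = "oral", dose = 3,
                  times = c(0.25, 0.5, 1, 2, 4, 7, 24),
                  conc = c(0.1, 5, 20, 10, 0.2, 3, 0.1), lloq = 0.4)
  q <- preprocess_blq(p)
  expect_equal(q$conc[1], 0)                       # leading BLQ -> 0
  expect_false(24 %in% q$times)                    # trailing BLQ dropped
  expect_false(4 %in% q$times)                     # embedded BLQ dropped
  expect_equal(length(q$times), 5L)
  expect_match(q$blq_note, "1 leading")
  # no BLQ: identity
  clean <- mono_profile()
  expect_identical(preprocess_blq(clean), clean)
  # all BLQ: error
  flat <- pk_profile(route = "oral", dose = 3, times = c(1, 2),
                     conc = c(0.1, 0.1), lloq = 0.4)
  expect_error(preprocess_blq(flat), "below the LLOQ")
  # alternative rules
  expect_equal(preprocess_blq(p, "drop_all")$conc, c(5, 20, 10, 3))
  expect_equal(preprocess_blq(p, "zero_all")$conc[c(1, 5, 7)], c(0, 0, 0))
})

test_that("trapezoidal AUC: triangle, log-down exactness, guards", {
  tri <- list(times = c(0, 1, 2), conc = c(0, 10, 0))
  expect_equal(auc(tri, method = "linear"), c(auc = 10))
  # mono-exponential: log-down segments integrate exactly
  t <- c(0, 0.25, 0.5, 1, 2, 4, 7, 24)
  c0 <- 100; k <- 0.5
  p <- list(times = t, conc = c0 * exp(-k * t))
  analytic <- c0 / k * (1 - exp(-k * 24))
  expect_equal(unname(auc(p)), analytic, tolerance = 1e-6)
  # linear method overestimates a convex decay
  expect_gt(auc(p, method = "linear"), analytic)
  expect_error(auc(list(times = 1, conc = 5)), "at least 2")
  # linear AUC invariant to interpolating a point onto a linear segment
  seg <- list(times = c(0, 2, 4), conc = c(0, 8, 2))
  seg2 <- list(times = c(0, 1, 2, 4), conc = c(0, 4, 8, 2))
  expect_equal(auc(seg, method = "linear"), auc(seg2, method = "linear"))
})

test_that("terminal slope fitting: exact, degenerate and noisy cases", {
  p <- mono_profile(k = 0.5)
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.5, tolerance = 1e-9)
  expect_equal(fit$t_half, log(2) / 0.5, tolerance = 1e-9)
  expect_true(fit$reliable)
  # flat profile: slope ~ 0 flagged unreliable
  flat <- pk_profile(route = "iv_bolus", dose = 1, times = 1:5,
                     conc = rep(10, 5), lloq = 0)
  ffit <- fit_lambda_z(flat)
  expect_lt(abs(ffit$lambda_z), 1e-10)
  expect_false(ffit$reliable)
  expect_error(fit_lambda_z(mono_profile(times = c(1, 2))), "terminal")
  # noisy mono-exponential recovers lambda within 10%
  cfg <- pk_sim_config(noise_cv = 0.10, seed = 11)
  noisy <- simulate_iv(cfg)
  k_true <- cfg$CL * 0.06 / cfg$V
  expect_lt(abs(fit_lambda_z(noisy)$lambda_z / k_true - 1), 0.10)
})

test_that("NCA on an exact bolus recovers CL, Vss, half-life and AUC order", {
  cfg <- pk_sim_config(noise_cv = 0)
  r <- nca(simulate_iv(cfg))
  expect_equal(r$cl, cfg$CL, tolerance = 1e-6)
  expect_equal(r$vss, cfg$V, tolerance = 1e-6)
  k <- cfg$CL * 0.06 / cfg$V
  expect_equal(r$t_half, log(2) / k, tolerance = 1e-6)
  expect_gte(r$auc_inf, r$auc_last)
  expect_equal(r$auc_dose_normalized, r$auc_inf / cfg$dose)
})

test_that("Cmax and Tmax come from the observed points", {
  obs <- pk_profile(route = "oral", dose = 3,
                    times = c(0.25, 0.5, 1, 2, 4, 7, 24),
                    conc = c(183, 150, 100, 50, 20, 8, 0.5), lloq = 0)
  r <- nca(obs)
  expect_equal(r$cmax, 183)
  expect_equal(r$tmax, 0.25)
  expect_true(is.na(r$cl) && is.na(r$vss))   # oral: no CL/Vss
})

test_that("unit conversion to ng/mL requires the molecular weight", {
  p <- mono_profile(conc_unit = "nM")
  expect_error(nca(p), "molecular_weight")
  p2 <- mono_profile(conc_unit = "nM", molecular_weight = 648.9)
  expect_s3_class(nca(p2), "nca_result")
})

test_that("oral bioavailability reproduces printed ratios and invariances", {
  expect_equal(round(oral_bioavailability(214, 544), 1), 39.3)
  expect_equal(round(oral_bioavailability(59, 257), 1), 23.0)
  expect_equal(oral_bioavailability(214, 544), 100 * 214 / 544)
  expect_equal(oral_bioavailability(100, 100), 100)
  # invariant under common rescaling of concentration units
  expect_equal(oral_bioavailability(214 * 648.9e-3, 544 * 648.9e-3),
               oral_bioavailability(214, 544))
  expect_error(oral_bioavailability(10, 0), "must be > 0")
})

test_that("first-pass arithmetic matches the portal/jugular AUC ratio", {
  fp <- first_pass(449, 104)
  expect_equal(fp$first_pass_pct, 100 * (1 - 104 / 449))
  expect_equal(round(fp$first_pass_pct, 1), 76.8)
  expect_equal(fp$hepatic_extraction_flag, "high")
  expect_equal(fp$implied_hepatic_cl,
               (1 - 104 / 449) * 90, tolerance = 1e-12)
  # complementarity is exact
  expect_equal(fp$first_pass_pct + 100 * fp$auc_jugular / fp$auc_portal, 100)
  # the Abu analogue's printed AUCs give ~10%
  expect_equal(round(first_pass(1839, 1656)$first_pass_pct, 1), 10.0)
  expect_equal(first_pass(300, 300)$first_pass_pct, 0)
  neg <- first_pass(100, 120)
  expect_true(neg$negative_extraction)
  expect_lt(neg$first_pass_pct, 0)       # reported, not clipped
  expect_equal(neg$hepatic_extraction_flag, "negative")
})

test_that("profile-level first pass clips to the common window and validates", {
  cfg <- pk_sim_config(noise_cv = 0)
  pair <- simulate_oral_paired(cfg)
  fp <- first_pass(pair$portal, pair$jugular)
  expect_gt(fp$first_pass_pct, 0)
  expect_lt(fp$first_pass_pct, 100)
  iv <- simulate_iv(cfg)
  expect_error(first_pass(pair$portal, iv), "oral")
  other <- pair$jugular
  other$dose <- 99
  expect_error(first_pass(pair$portal, other), "share subject and dose")
})

test_that("PK CSV round-trips profiles through the documented dialect", {
  cfg <- pk_sim_config(noise_cv = 0.2, seed = 3)
  pair <- simulate_oral_paired(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_csv(list(pair$portal, pair$jugular), path)
  back <- read_pk_csv(path)
  expect_length(back, 2L)
  portal <- back[[grep("portal", names(back))]]
  expect_equal(portal$conc, pair$portal$conc)
  expect_equal(portal$times, pair$portal$times)
  expect_equal(portal$lloq, 0.4)
})
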