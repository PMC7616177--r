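test_that("noiseless saturation isotherms are recovered exactly", {
  d <- gen_binding_assay("saturation", list(KD = 1e-9, Bmax = 500),
                         grid = 10^seq(-10.5, -7.5, 0.5), noise_sd = 0)
  f <- fit_saturation(d$conc_M, d$total_dpm, d$nsb_dpm)
  expect_true(f$converged)
  expect_equal(f$KD, 1e-9, tolerance = 1e-6)
  expect_equal(f$Bmax, 500, tolerance = 1e-6)
  # model identity: specific binding at the fitted KD is Bmax/2
  expect_equal(f$Bmax * f$KD / (f$KD + f$KD), f$Bmax / 2, tolerance = 1e-9)
  # no approach to saturation is flagged
  d2 <- gen_binding_assay("saturation", list(KD = 1e-7, Bmax = 500),
                          grid = 10^seq(-10.5, -8.5, length.out = 6),
                          noise_sd = 0)
  expect_true(fit_saturation(d2$conc_M, d2$total_dpm, d2$nsb_dpm)$extrapolated)
})

test_that("competition fits return the exact pIC50 and detect flat data", {
  grid <- 10^seq(-10, -3.5, 0.75)
  d <- gen_binding_assay("competition",
                         list(Ki = 2e-5, L = 3e-10, KD = 3e-10),
                         grid = grid, noise_sd = 0)
  f <- fit_competition(log10(d$inhibitor_conc_M), d$bound)
  expect_equal(f$pIC50, -log10(4e-5), tolerance = 1e-6)  # IC50 = 2 Ki = 40 uM
  # flat data: "no binding", not a fit failure
  set.seed(4)
  flat <- fit_competition(log10(grid), 100 + rnorm(length(grid), 0, 1))
  expect_true(flat$no_binding)
  expect_true(flat$converged)
})

test_that("noisy competition recovers pIC50 4.4 on average", {
  p <- vapply(1:40, function(i) {
    d <- gen_binding_assay("competition",
                           list(Ki = 10^-4.4 / 2, L = 3e-10, KD = 3e-10),
                           grid = 10^seq(-10, -3.5, 0.75), noise_sd = 0.05,
                           seed = 100 + i)
    fit_competition(log10(d$inhibitor_conc_M), d$bound)$pIC50
  }, numeric(1))
  expect_lt(abs(mean(p) - 4.4), 0.1)
})

test_that("Cheng-Prusoff arithmetic and limits are exact", {
  expect_equal(cheng_prusoff(4e-5, 1e-15, 3e-10)$Ki, 4e-5, tolerance = 1e-5)
  cp <- cheng_prusoff(4e-5, 3e-10, 3e-10)  # L = KD halves the IC50
  expect_equal(cp$Ki, 2e-5, tolerance = 1e-9)
  expect_equal(cp$pKi, -log10(4e-5) + log10(2), tolerance = 1e-9)
  expect_equal(round(cp$pKi, 2), 4.70)
  # Ki decreases monotonically with L at fixed IC50
  Ls <- c(1e-11, 1e-10, 1e-9, 1e-8)
  Kis <- vapply(Ls, function(L) cheng_prusoff(4e-5, L, 3e-10)$Ki, numeric(1))
  expect_true(all(diff(Kis) < 0))
  expect_error(cheng_prusoff(-1, 1e-10, 1e-10), class = "pharmfit_input_error")
})

test_that("saturation and competition analyses are mutually consistent", {
  sat <- gen_binding_assay("saturation", list(KD = 3e-10, Bmax = 800),
                           grid = 10^seq(-11, -8.7, length.out = 8),
                           noise_sd = 0.03, seed = 7)
  fs <- fit_saturation(sat$conc_M, sat$total_dpm, sat$nsb_dpm)
  true_Ki <- 2e-6
  comp <- gen_binding_assay("competition",
                            list(Ki = true_Ki, L = 3e-10, KD = 3e-10),
                            grid = 10^seq(-9.5, -3.5, length.out = 10),
                            noise_sd = 0.03, seed = 8)
  fc <- fit_competition(log10(comp$inhibitor_conc_M), comp$bound)
  ki <- cheng_prusoff(fc$IC50, 3e-10, fs$KD)
  expect_equal(ki$pKi, -log10(true_Ki), tolerance = 0.1)
})

test_that("dissociation kinetics recover koff and the half-life identity", {
  d <- gen_binding_assay("dissociation", list(B0 = 1000, koff = 0.0693),
                         grid = seq(0, 60, 5), noise_sd = 0)
  f <- fit_dissociation(d$time_min, d$bound)
  expect_equal(f$koff, 0.0693, tolerance = 1e-6)
  expect_equal(f$half_life, log(2) / 0.0693, tolerance = 1e-6)
  expect_equal(f$half_life, 10, tolerance = 1e-2)
  # generator half-life sanity: bound at t = ln2/koff is B0/2
  d2 <- gen_binding_assay("dissociation", list(B0 = 600, koff = 0.1),
                          grid = c(0, 6.93, 20, 40, 60), noise_sd = 0)
  expect_equal(d2$bound[2], 300, tolerance = 0.5)
  # rising time course rejected
  expect_error(fit_dissociation(seq(0, 40, 5), seq(100, 500, 50)),
               class = "pharmfit_input_error")
})

test_that("koff ratio test has controlled error rates", {
  flags_null <- vapply(1:30, function(i) {
    d1 <- gen_binding_assay("dissociation", list(B0 = 1000, koff = 0.08),
                            grid = seq(0, 50, 5), noise_sd = 0.05,
                            seed = 100 + i)
    d2 <- gen_binding_assay("dissociation", list(B0 = 1000, koff = 0.08),
                            grid = seq(0, 50, 5), noise_sd = 0.05,
                            seed = 5000 + i, condition = "test")
    f1 <- fit_dissociation(d1$time_min, d1$bound)
    f2 <- fit_dissociation(d2$time_min, d2$bound, condition = "test")
    compare_dissociation(f1, f2, n_boot = 150, seed = i)$kinetics_altered
  }, logical(1))
  expect_lte(mean(flags_null), 0.1)  # near-nominal type I error

  flags_alt <- vapply(1:30, function(i) {
    d1 <- gen_binding_assay("dissociation", list(B0 = 1000, koff = 0.05),
                            grid = seq(0, 50, 5), noise_sd = 0.05,
                            seed = 200 + i)
    d2 <- gen_binding_assay("dissociation", list(B0 = 1000, koff = 0.10),
                            grid = seq(0, 50, 5), noise_sd = 0.05,
                            seed = 7000 + i, condition = "test")
    f1 <- fit_dissociation(d1$time_min, d1$bound)
    f2 <- fit_dissociation(d2$time_min, d2$bound, condition = "test")
    compare_dissociation(f1, f2, n_boot = 150, seed = i)$kinetics_altered
  }, logical(1))
  expect_gte(mean(flags_alt), 0.9)  # power at a two-fold koff change
})

test_that("dpm conversion uses 2.22 dpm per fCi exactly", {
  expect_identical(dpm_to_fmol_per_mg(0, 48.01, 0.01), 0)
  # 48.01 Ci/mmol is 106.58 dpm/fmol
  expect_equal(48.01 * 2.22, 106.5822, tolerance = 1e-9)
  expect_equal(dpm_to_fmol_per_mg(2131.6, 48.01, 0.01), 2000, tolerance = 1e-3)
  expect_error(dpm_to_fmol_per_mg(100, 48.01, 0), class = "pharmfit_input_error")
})
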