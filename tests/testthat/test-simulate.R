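test_that("zero-noise generators return the model exactly; seeds are honored", {
  tr <- list(bottom = 0, top = 100, pEC50 = 7, hill = 1)
  cg <- conc_grid(1e-10, 1e-4, 8)
  cv0 <- gen_dose_response(tr, conc = cg, replicates = 2, noise_sd = 0, seed = 1)
  expect_equal(cv0$response, rep(hill4(cg, 0, 100, 7, 1), 2), tolerance = 1e-12)
  a <- gen_dose_response(tr, conc = cg, noise_sd = 0.05, seed = 42)
  b <- gen_dose_response(tr, conc = cg, noise_sd = 0.05, seed = 42)
  c <- gen_dose_response(tr, conc = cg, noise_sd = 0.05, seed = 43)
  expect_identical(a$response, b$response)
  expect_false(identical(a$response, c$response))
  # noiseless values never depend on the seed
  expect_identical(gen_dose_response(tr, conc = cg, noise_sd = 0, seed = 1)$response,
                   gen_dose_response(tr, conc = cg, noise_sd = 0, seed = 99)$response)
})

test_that("adding replicates never perturbs existing replicate streams", {
  tr <- list(bottom = 0, top = 100, pEC50 = 7, hill = 1)
  cg <- conc_grid(1e-10, 1e-4, 8)
  two <- gen_dose_response(tr, conc = cg, replicates = 2, noise_sd = 0.05,
                           seed = 5)
  four <- gen_dose_response(tr, conc = cg, replicates = 4, noise_sd = 0.05,
                            seed = 5)
  expect_identical(two$response, four$response[seq_along(two$response)])
})

test_that("replicate noise averages to the model value", {
  tr <- list(bottom = 0, top = 100, pEC50 = 7, hill = 1)
  one_conc <- 1e-7  # at the EC50: mean response 50
  cv <- gen_dose_response(tr, conc = rep(one_conc, 1), replicates = 10000,
                          noise_sd = 0.05, seed = 9)
  se <- sd(cv$response) / sqrt(length(cv$response))
  expect_lt(abs(mean(cv$response) - 50), 3 * se)
})

test_that("antagonism family honors the Gaddum shift and its control", {
  tr <- list(bottom = 0, top = 100, pEC50 = 7, hill = 1)
  fam <- gen_antagonism_family(tr, pKB = 6, B = c(0, 9e-6), noise_sd = 0,
                               replicates = 1, conc = conc_grid(1e-10, 1e-3, 10))
  ctrl <- fam[fam$antagonist_conc_M == 0, ]
  solo <- gen_dose_response(tr, conc = conc_grid(1e-10, 1e-3, 10),
                            replicates = 1, noise_sd = 0, seed = 1)
  expect_equal(ctrl$response, solo$response, tolerance = 1e-12)
  f0 <- fit_4pl(crc(ctrl$conc_M, ctrl$response))
  trt <- fam[fam$antagonist_conc_M > 0, ]
  f1 <- fit_4pl(crc(trt$conc_M, trt$response))
  expect_equal(dose_ratio(f0, f1), 10, tolerance = 1e-4)
  expect_error(gen_antagonism_family(tr, pKB = 6, B = c(1e-6)),
               class = "pharmfit_input_error")
})

test_that("partial-agonist mode raises the baseline by the closed-form amount", {
  ag <- list(Em = 100, Basal = 0, tau = 20, KA = 1e-6)
  B <- 1e-5; KB <- 1e-6; tau_B <- 0.5
  fam <- gen_antagonism_family(ag, pKB = -log10(KB), B = c(0, B),
                               mode = "partial_agonist", tau_B = tau_B,
                               noise_sd = 0, replicates = 1,
                               conc = conc_grid(1e-12, 1e-3, 10))
  base <- fam[fam$antagonist_conc_M == B & fam$conc_M == min(fam$conc_M), ]
  # at vanishing agonist the response is the antagonist's own effect
  rhoB <- (B / KB) / (1 + B / KB)
  expected <- 100 * tau_B * rhoB / (1 + tau_B * rhoB)
  expect_equal(base$response, expected, tolerance = 1e-3)
})

test_that("competition generator encodes the Cheng-Prusoff forward relation", {
  d <- gen_binding_assay("competition",
                         list(Ki = 1e-6, L = 3e-10, KD = 3e-10),
                         grid = c(2e-6), noise_sd = 0)
  # at I = IC50 = 2 Ki the curve is at half-span
  expect_equal(d$bound, 50, tolerance = 1e-9)
})

test_that("saturation generator puts half of Bmax at KD", {
  d <- gen_binding_assay("saturation", list(KD = 6e-11, Bmax = 500,
                                            ns_slope = 0),
                         grid = c(6e-11), noise_sd = 0)
  expect_equal(d$total_dpm - d$nsb_dpm, 250, tolerance = 1e-9)
})

test_that("binding generators are seed-reproducible", {
  g <- 10^seq(-11, -8.7, length.out = 8)
  a <- gen_binding_assay("saturation", list(KD = 6e-11, Bmax = 500), g,
                         noise_sd = 0.08, seed = 3)
  b <- gen_binding_assay("saturation", list(KD = 6e-11, Bmax = 500), g,
                         noise_sd = 0.08, seed = 3)
  expect_identical(a, b)
  d1 <- gen_binding_assay("dissociation", list(B0 = 100, koff = 0.07),
                          seq(0, 60, 5), noise_sd = 0.05, seed = 2)
  d2 <- gen_binding_assay("dissociation", list(B0 = 100, koff = 0.07),
                          seq(0, 60, 5), noise_sd = 0.05, seed = 2)
  expect_identical(d1, d2)
})

test_that("generator-fitter closure holds at 5% noise", {
  # every generator kind, matched to its fitter, recovers truth within a
  # tolerance band across seeds
  pec <- vapply(1:25, function(i)
    fit_4pl(sim_pl4(7.49, seed = i))$coefficients[["pEC50"]], numeric(1))
  expect_lt(abs(mean(pec) - 7.49), 0.05)
  kds <- vapply(1:25, function(i) {
    d <- gen_binding_assay("saturation", list(KD = 6e-11, Bmax = 500),
                           10^seq(log10(5e-12), log10(2e-9), length.out = 8),
                           noise_sd = 0.05, seed = i)
    fit_saturation(d$conc_M, d$total_dpm, d$nsb_dpm)$KD
  }, numeric(1))
  expect_lt(abs(exp(mean(log(kds))) / 6e-11 - 1), 0.15)
  koffs <- vapply(1:25, function(i) {
    d <- gen_binding_assay("dissociation", list(B0 = 1000, koff = 0.07),
                           seq(0, 60, 5), noise_sd = 0.05, seed = i)
    fit_dissociation(d$time_min, d$bound)$koff
  }, numeric(1))
  expect_lt(abs(mean(koffs) / 0.07 - 1), 0.05)
})

test_that("depletion generator matches the closed-form plateau ratios", {
  dep <- gen_depletion_experiment(
    list(full = list(tau = 30, KA = 1e-6)), q = 1, noise_sd = 0,
    replicates = 1)
  ctrl <- dep[dep$depletion == "control", "response"]
  dpl <- dep[dep$depletion == "depleted", "response"]
  expect_identical(ctrl, dpl)  # q = 1: identical at zero noise
})
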