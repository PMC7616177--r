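test_that("noiseless closed-form identities hold on the fitted model", {
  # tau = 4, KA = 1 uM, Em = 100, n = 1: half-max at KA/(1+tau) = 200 nM,
  # plateau Em*tau/(1+tau) = 80
  cg <- conc_grid(1e-10, 1e-3, 12)
  ref <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 30, KA = 1e-6),
                           "operational", cg, 1, 0, 1, "ref", "P")
  tst <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 4, KA = 1e-6),
                           "operational", cg, 1, 0, 1, "tst", "P")
  f <- fit_operational_global(list(ref, tst), "ref")
  expect_true(f$converged)
  e <- f$ligands[f$ligands$ligand == "tst", ]
  pred <- function(A) {
    tau <- 10^(e$log_R + e$log_KA); KA <- 10^e$log_KA
    sys <- f$system
    sys$Basal + (sys$Em - sys$Basal) * (tau * A)^sys$n /
      ((A + KA)^sys$n + (tau * A)^sys$n)
  }
  expect_equal(pred(1e3), 80, tolerance = 1e-6)
  expect_equal(pred(2e-7), 40, tolerance = 1e-6)
})

test_that("nested-model consistency: operational and 4PL agree on EC50", {
  cg <- conc_grid(1e-11, 1e-4, 12)
  ref <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 50, KA = 1e-6),
                           "operational", cg, 1, 0, 1, "ref", "P")
  tst <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 2, KA = 3e-6),
                           "operational", cg, 1, 0, 1, "tst", "P")
  f <- fit_operational_global(list(ref, tst), "ref")
  f4 <- fit_4pl(tst)
  e <- f$ligands[f$ligands$ligand == "tst", ]
  ec50_op <- 10^e$log_KA / (1 + 10^(e$log_R + e$log_KA))
  expect_equal(ec50_op / f4$ec50, 1, tolerance = 1e-4)
})

test_that("two-ligand transduction-coefficient difference is recovered under noise", {
  dd <- vapply(1:30, function(i) {
    cg <- conc_grid(1e-10, 1e-4, 9)
    r <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, log_R = 8, log_KA = -6),
                           "operational", cg, 2, 0.05, 300 + i, "ref", "P")
    t <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, log_R = 6.5, log_KA = -6),
                           "operational", cg, 2, 0.05, 600 + i, "tst", "P")
    f <- fit_operational_global(list(r, t), "ref")
    f$ligands$log_R[f$ligands$ligand == "tst"] -
      f$ligands$log_R[f$ligands$ligand == "ref"]
  }, numeric(1))
  expect_lt(abs(mean(dd) - (-1.5)), 0.1)
})

test_that("full agonists are flagged KA-unidentifiable", {
  cg <- conc_grid(1e-11, 1e-4, 12)
  r <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 100, KA = 1e-6),
                         "operational", cg, 1, 0, 1, "ref", "P")
  t <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 0.8, KA = 1e-7),
                         "operational", cg, 1, 0, 1, "tst", "P")
  f <- fit_operational_global(list(r, t), "ref")
  expect_true(f$ligands$ka_unidentifiable[f$ligands$ligand == "ref"])
  expect_false(f$ligands$ka_unidentifiable[f$ligands$ligand == "tst"])
})

test_that("ligand input order does not change the fitted parameters", {
  cg <- conc_grid(1e-10, 1e-4, 9)
  r <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 30, KA = 1e-6),
                         "operational", cg, 2, 0.04, 21, "A", "P")
  t <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 2, KA = 1e-6),
                         "operational", cg, 2, 0.04, 22, "B", "P")
  f1 <- fit_operational_global(list(r, t), "A")
  f2 <- fit_operational_global(list(t, r), "A")
  m1 <- f1$ligands[order(f1$ligands$ligand), c("log_R", "log_KA")]
  m2 <- f2$ligands[order(f2$ligands$ligand), c("log_R", "log_KA")]
  expect_equal(as.matrix(m1), as.matrix(m2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("single-ligand and cross-pathway inputs are rejected", {
  cg <- conc_grid(1e-10, 1e-4, 9)
  r <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 30, KA = 1e-6),
                         "operational", cg, 2, 0.04, 31, "A", "P")
  expect_error(fit_operational_global(list(r), "A"),
               class = "pharmfit_input_error")
  t2 <- gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 2, KA = 1e-6),
                          "operational", cg, 2, 0.04, 32, "B", "Q")
  expect_error(fit_operational_global(list(r, t2), "A"),
               class = "pharmfit_input_error")
  e1 <- data.frame(ligand = "B", log_R = 6, se_log_R = 0.1, pathway = "P")
  e2 <- data.frame(ligand = "A", log_R = 8, se_log_R = 0.2, pathway = "Q")
  expect_error(delta_log_r(e1, e2), class = "pharmfit_input_error")
})

test_that("delta and delta-delta arithmetic is exact", {
  ref <- data.frame(ligand = "A", log_R = 8, se_log_R = 0.2, pathway = "P")
  tst <- data.frame(ligand = "B", log_R = 6.5, se_log_R = 0.1, pathway = "P")
  d <- delta_log_r(tst, ref)
  expect_equal(d$delta, -1.5)
  expect_equal(d$sem, sqrt(0.1^2 + 0.2^2), tolerance = 1e-9)
  # reference vs itself: 0 with sqrt(2)-inflated SEM
  d0 <- delta_log_r(ref, ref)
  expect_identical(d0$delta, 0)
  expect_equal(d0$sem, 0.2 * sqrt(2), tolerance = 1e-9)
  # more efficient test ligand gives positive delta
  up <- delta_log_r(transform(tst, log_R = 9), ref)
  expect_gt(up$delta, 0)

  deltas <- data.frame(pathway = c("Gq", "arrestin"),
                       delta = c(0.3, -0.2), sem = c(0.1, 0.1))
  dd <- delta_delta_log_r(deltas)
  ij <- dd[dd$pathway_i == "Gq" & dd$pathway_j == "arrestin", ]
  ji <- dd[dd$pathway_i == "arrestin" & dd$pathway_j == "Gq", ]
  expect_equal(ij$dd_log_r, 0.5)
  expect_equal(ij$sem, sqrt(0.02), tolerance = 1e-9)
  expect_equal(ij$bias_factor, 10^0.5, tolerance = 1e-9)
  expect_identical(ij$dd_log_r, -ji$dd_log_r)  # exact antisymmetry
  # identical deltas: no bias
  same <- delta_delta_log_r(data.frame(pathway = c("a", "b"),
                                       delta = c(0.4, 0.4),
                                       sem = c(0.1, 0.1)))
  expect_equal(same$dd_log_r, c(0, 0))
  expect_equal(same$bias_factor, c(1, 1))
  # missing pathway dropped with a message
  expect_message(
    delta_delta_log_r(data.frame(pathway = c("a", "b", "c"),
                                 delta = c(0.1, NA, 0.3),
                                 sem = c(0.1, 0.1, 0.1))),
    "omitting")
})

test_that("bias flags follow the one-log-unit window", {
  tab <- data.frame(pathway_i = c("a", "a", "b"), pathway_j = c("b", "c", "c"),
                    dd_log_r = c(0, 0.4, 1.3), sem = 0.1,
                    bias_factor = 10^c(0, 0.4, 1.3))
  flagged <- assess_bias(tab)
  expect_identical(flagged$unbiased, c(TRUE, TRUE, FALSE))
  expect_false(attr(flagged, "overall_unbiased"))
  expect_true(all(assess_bias(tab, threshold = 1.5)$unbiased))
})

test_that("a zero-bias agonist is called unbiased across three pathways", {
  hits <- vapply(1:25, function(i) {
    paths <- c("Gq", "pERK", "arrestin")
    dat <- do.call(rbind, lapply(seq_along(paths), function(k) {
      ref <- gen_dose_response(
        list(Em = 100, Basal = 0, n = 1, tau = 30, KA = 10^-6.5),
        "operational", conc_grid(1e-10, 1e-4, 9), 2, 0.05,
        seed = i * 100 + k, ligand = "ACh", pathway = paths[k])
      tst <- gen_dose_response(
        list(Em = 100, Basal = 0, n = 1, tau = 3, KA = 10^-6.8),
        "operational", conc_grid(1e-10, 1e-4, 9), 2, 0.05,
        seed = i * 100 + 50 + k, ligand = "HTL", pathway = paths[k])
      rbind(as.data.frame(ref), as.data.frame(tst))
    }))
    bt <- compute_bias(dat, reference = "ACh")
    max(abs(bt$delta_delta$HTL$dd_log_r)) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("receptor reserve shapes the depletion signature", {
  # high-reserve full agonist vs the same ligand at 100x lower tau:
  # both potency and maximum fall
  cg <- conc_grid(1e-10, 1e-3, 12)
  hi <- fit_4pl(gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 30,
                                       KA = 1e-6), "operational", cg, 1, 0, 1))
  lo <- fit_4pl(gen_dose_response(list(Em = 100, Basal = 0, n = 1, tau = 0.3,
                                       KA = 1e-6), "operational", cg, 1, 0, 1))
  expect_lt(lo$emax, hi$emax)
  expect_lt(lo$coefficients[["pEC50"]], hi$coefficients[["pEC50"]])
})
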