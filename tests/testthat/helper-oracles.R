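# Shared truths and independent oracles used across the suite.

# 4PL mean function (independent re-statement, used to build fixtures)
hill4 <- function(A, bottom, top, pEC50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (-pEC50 - log10(A))))
}

# operational mean function, n = 1 closed form
op1 <- function(A, Em, tau, KA, basal = 0) {
  basal + (Em - basal) * tau * A / (A + KA + tau * A)
}

# Brute-force 4PL grid-search oracle: SSR minimized over a (pEC50, hill)
# grid with the conditionally-linear bottom/top solved analytically at each
# node. Independent of the package's optimizer.
grid_search_4pl <- function(x, y, pec50s = seq(5, 9, 0.01),
                            hills = seq(0.5, 2, 0.01)) {
  best <- c(ssr = Inf, pEC50 = NA, hill = NA)
  for (p in pec50s) {
    for (h in hills) {
      g <- 1 / (1 + 10^(h * (-p - x)))
      fit <- stats::lm.fit(cbind(1, g), y)
      ssr <- sum(fit$residuals^2)
      if (ssr < best["ssr"]) best <- c(ssr = ssr, pEC50 = p, hill = h)
    }
  }
  best
}

# quick simulated curve around a 4PL truth
sim_pl4 <- function(pEC50, top = 100, bottom = 0, hill = 1,
                    conc = conc_grid(1e-10, 1e-4, 8), replicates = 3,
                    noise_sd = 0.05, seed = 1, ...) {
  gen_dose_response(list(bottom = bottom, top = top, pEC50 = pEC50,
                         hill = hill),
                    conc = conc, replicates = replicates,
                    noise_sd = noise_sd, seed = seed, ...)
}
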