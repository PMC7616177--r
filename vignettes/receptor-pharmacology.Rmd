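---
title: "Quantitative receptor pharmacology with pharmfit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative receptor pharmacology with pharmfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmfit)
```

pharmfit implements the quantitative analyses used to characterize a GPCR
agonist program end to end: concentration-response fitting, operational-model
ligand-bias quantification, Schild antagonism analysis, radioligand-binding
analyses, receptor-depletion (Furchgott) efficacy estimation, and the
unbound-exposure arithmetic that connects in vitro potency to in vivo dosing.
This vignette explains each model, its assumptions, the tunable parameters
that matter, and the numerical and design decisions behind the
implementation.

## Concentration-response curves: the 4PL model

Agonist curves are fitted with the four-parameter logistic (Hill) model

$$E(A) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{\,h\,(\mathrm{pEC_{50}}\;-\;(-\log_{10} A))\cdot(-1)}}$$

equivalently $E = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})\,
A^h/(A^h + \mathrm{EC_{50}}^h)$. Fitting happens in log10-concentration
space with pEC50 ($-\log_{10}$ molar EC50) as the free potency parameter:
on designs spanning three or more decades this is far better conditioned
than fitting EC50 directly. Concentrations are stored internally in molar
whatever unit they arrive in (`crc()` converts nM, µM, log10 M, ...), so a
potency is always a `-log10 M` quantity.

Numerical choices:

* **Initialization** is deterministic — bottom = min response, top = max
  response, pEC50 at the half-range crossing of the concentration-averaged
  responses, Hill slope 1. No random restarts, so a fit is exactly
  reproducible.
* **Bounds**: Hill slope in [0.3, 5]; pEC50 within the data's
  log-concentration range widened by 2 log units; bottom/top unbounded
  unless the caller constrains them. These prevent pathological fits on
  truncated curves while leaving well-determined problems untouched.
* **Optimizer**: Levenberg-Marquardt least squares (minpack.lm) with tight
  tolerances (`ftol = ptol = 1e-13`), which recovers noiseless truths to
  numerical precision.
* **Standard errors** come from the local curvature (Gauss-Newton
  approximation) at the optimum; a seeded residual-bootstrap alternative is
  available via `fit_4pl(..., bootstrap = TRUE)` for small designs where
  curvature-based SEs are optimistic.
* Replicates are pooled with equal weights, matching the usual
  "performed in duplicate" designs; experiments are summarized afterwards
  with `potency_summary()`, which averages pEC50 on the log scale (i.e.
  reports a geometric-mean EC50). Published potencies rarely state whether
  they are geometric means across experiments or pooled-fit estimates; the
  geometric mean is this package's default reading, and pooled fits remain
  available simply by concatenating the data.
* A fit whose EC50 lands above one third of the highest tested
  concentration is flagged `top_extrapolated`: the plateau was not
  approached and `top` (hence Emax) rests on extrapolation.

Degenerate inputs are separated deliberately: fewer than four distinct
concentrations is an input error; flat responses raise a "no fit" condition
(class `pharmfit_no_fit_error`) distinct from solver non-convergence, which
returns a flagged fit object rather than silent numbers.

Thermal-stability curves use the same machinery with a descending logistic
in temperature; `fit_thermal_melt()` reports Tm as the temperature at which
the fitted curve retains 50% of its full (low-temperature) binding — found
on the fitted curve, never by linear interpolation between points.

## Operational-model bias analysis

The Black–Leff operational model writes the response as

$$E(A) = \mathrm{Basal} + (E_m - \mathrm{Basal})\,
\frac{(\tau A)^n}{(A + K_A)^n + (\tau A)^n}$$

where $\tau$ is the operational efficacy (receptor density times coupling
efficiency), $K_A$ the functional dissociation constant, $E_m$ the maximal
response the system can produce, and $n$ the transducer slope. The quantity
interpreted for bias is the transduction coefficient
$\log(\tau/K_A)$, which `fit_operational_global()` fits *directly* (together
with $\log K_A$) for every ligand while sharing $E_m$, Basal and $n$ across
ligands within a pathway. Sharing $n$ is standard transduction-coefficient
practice and is required for identifiability; Basal is fitted rather than
fixed at zero unless the data are reference-normalized (`fix_basal = 0`).

Two identifiability limits deserve explicit handling:

* **Full agonists**: when a ligand's plateau reaches within 2% of $E_m$,
  $\tau$ and $K_A$ trade off freely and only their ratio is determined. The
  entry is flagged `ka_unidentifiable`; $\log(\tau/K_A)$ remains valid.
* **$E_m$**: agonist curves alone cannot pin the system maximum far above
  the largest observed response — the model otherwise degenerates toward a
  plain logistic with absurd $E_m$. $E_m$ is therefore bounded within
  [max − 0.25·span, max + 0.5·span] of the observed responses, which
  presumes a (near-)full agonist reference is present in every pathway, as
  in any well-designed bias experiment. Parameters may still drift slightly
  along the $E_m$–$\tau$ ridge on noiseless data; the fitted curve, the
  implied EC50 $K_A/(1+\tau)$, the plateau, and above all the
  *differences* of transduction coefficients are insensitive to it (the
  test suite asserts those invariants rather than raw $E_m$).

Bias is then pure arithmetic with exact error propagation:

* $\Delta\log(\tau/K_A)$ = test − reference within a pathway, SEM in
  quadrature: $\sqrt{SE_t^2 + SE_r^2}$;
* $\Delta\Delta\log(\tau/K_A)$ = $\Delta_i - \Delta_j$ across pathway
  pairs, SEM again in quadrature, bias factor $10^{\Delta\Delta}$. Whether
  a published analysis used one anchor pathway or all pairs is usually
  ambiguous, so `delta_delta_log_r()` computes every ordered pair (the
  table is exactly antisymmetric) and reports print the upper triangle.
* `assess_bias()` applies a threshold window, 1.0 log units by default —
  an entry is unbiased iff $|\Delta\Delta| \le 1$ (a ten-fold bias factor
  window), a ligand unbiased overall iff all entries are. The flags are
  threshold-based by design; no p-value machinery or multiplicity
  correction is applied, and the report says so.

## Schild analysis of surmountable antagonism

For a competitive antagonist at concentration $[B]$ the Gaddum relation
shifts the agonist EC50 by the dose ratio $DR = 1 + [B]/K_B$.
`schild_analysis()` fits a 4PL per antagonist concentration, computes
$DR = EC_{50,B}/EC_{50,0}$, and regresses $\log_{10}(DR-1)$ on
$\log_{10}[B]$ — the classical Schild regression. The free-slope
x-intercept gives pA2; refitting with slope fixed at 1 gives the
constrained pK~B~ (the mean of $\log_{10}(DR-1) - \log_{10}[B]$). Both are
reported, because a published pA2 may come from either; a slope near unity
is itself the diagnostic of simple competition. Points with $DR \le 1$
carry no information on the log(DR−1) scale and are excluded with a logged
warning — noise at low $[B]$ routinely produces DR ≈ 1 and failing the whole
regression for it would be wrong. The interacting ligand's own partial
agonism is ignored at the analysis stage (it is treated purely as a
competitive antagonist), matching interaction designs run under receptor
depletion; the simulator's `partial_agonist` mode exists to test the
robustness of that simplification.

## Radioligand binding

All binding analyses are one-site with Hill slope fixed at ±1 (two-site
models are out of scope):

* **Saturation**: specific binding (total − matched NSB, point-wise) is fitted
  to $B_{max}L/(K_D+L)$; the non-specific channel is modeled as linear
  through the origin. A fitted $K_D$ above the highest tested concentration
  flags the result as extrapolated.
* **Competition**: descending one-site logistic; pIC50 converted with
  Cheng–Prusoff, $K_i = IC_{50}/(1 + L/K_D)$ — run with the radioligand at
  its $K_D$, this is exactly $IC_{50}/2$. A response span below three times
  the estimated measurement noise returns a "no binding" result (how a
  subtype with no detectable affinity should read out) distinct from a fit
  failure.
* **Dissociation kinetics**: mono-exponential decay, $t_{1/2} = \ln 2 /
  k_{off}$. Because the classical two-condition design (dissociation with
  and without a putative allosteric ligand) is usually described without an
  accompanying statistic, `compare_dissociation()` uses a seeded
  residual-bootstrap CI on the $k_{off}$ ratio and flags "kinetics altered"
  when the CI excludes 1.
* **Unit conversion**: `dpm_to_fmol_per_mg()` uses 1 Ci = 2.22×10^12 dpm,
  so a specific activity in Ci/mmol is numerically dpm per fmol after
  multiplying by 2.22.

## Receptor depletion and intrinsic efficacy

Irreversible alkylation (e.g. phenoxybenzamine) removes a fraction of the
receptor pool. Under the operational model this is pure $\tau$-scaling at
fixed $K_A$ (the Furchgott assumption): if a fraction $q$ of receptors
survives, $\tau \to q\tau$. `fit_depletion_pair()` jointly fits control and
depleted curves sharing $K_A$, $E_m$, Basal, $n$ with a free $\tau$ per
condition and reports $q = \tau_{post}/\tau_{pre}$ with a delta-method SE.
Because alkylation acts on the receptor pool and not on any one ligand,
curves from ligands treated in the same batch share $q$;
`fit_depletion_batch()` implements that common-$q$ joint fit and is the
natural choice whenever a batch label is available. $E_m$ is best anchored
by a pre-depletion full agonist (pass `system = list(Em = ...)`); when
co-fitted it is bounded near the observed maximum and the result flagged.

The closed-form plateau $E_m\,q\tau/(1+q\tau)$ explains the hallmark
observation that partial agonists are more sensitive to depletion: for
fixed $q<1$ the fractional plateau drop is strictly larger for smaller
$\tau$ (for $q = 0.1$, a $\tau = 30$ full agonist keeps 77.5% of its
maximum while a $\tau = 1$ partial agonist keeps 18.2%). The alkylation
pharmacology itself (exposure, kinetics) is not modeled. Relative intrinsic
efficacy is the plain ratio $\tau_{test}/\tau_{ref}$ with a log-scale
quadrature SE.

## Translational exposure arithmetic

`mass_to_molar()`, `unbound_concentration()`, `brain_exposure_range()`,
`kpuu()` and `therapeutic_index()` are deliberately pure functions — same
inputs, bit-identical outputs — and `exposure_record()` chains them with a
dimensional-consistency audit (unbound ≤ total when fu ≤ 1; the CSF-scaled
brain range cannot exceed the plasma molar value when ratios ≤ 1; scaling
Cmax by $k$ scales every derived concentration by exactly $k$).

Two conventions are configurable and worth stating:

* The default molecular weight is 365.5 g/mol, the free-base weight
  consistent with an observed m/z of 366 (M+H)+ for the compound class this
  package was built around; it is a parameter everywhere, never a constant.
* Plasma fraction-unbound values are required inputs. Species fu values
  printed alongside published unbound exposures can often only be
  back-calculated (e.g. 6,400 ng/mL total with ~12,000 nM unbound implies
  fu ≈ 0.685 at MW 365.5); such values are documented as reverse-engineered
  defaults, never silently assumed.
* The apparent therapeutic index is computed on total plasma exposures — the
  conventional basis — with an unbound basis available by passing unbound
  values; the quotient is reported unrounded.
* CSF:plasma ratios are treated as a surrogate range for unbound brain
  concentration; reported range endpoints round to the nearest nM while
  exact values are retained. AUC-based CSF:plasma summaries require the
  underlying concentration-time data and are out of scope.

## The synthetic-data generators

Every analysis has a matched seeded generator (`gen_dose_response`,
`gen_antagonism_family`, `gen_binding_assay`, `gen_depletion_experiment`),
so the whole pipeline is testable with no external data. The generators
emulate the assay designs the analyses were built for: 8-point half-log
concentration grids, duplicate or triplicate wells, three to four
independent experiments per condition, additive Gaussian noise with sd
expressed as a fraction of the noiseless response span (published
variability is SEM-style, which this matches well enough for
parameter-recovery work). All randomness flows from one explicit integer
seed through named per-replicate substreams: noiseless model values never
depend on the seed, the same (design, seed) pair is byte-identical on
re-run, and adding replicates never perturbs existing ones.

What the generators do *not* emulate — plate/edge effects, heteroscedastic
scintillation counting statistics, receptor desensitization, hemi-equilibrium
artifacts — bounds what passing tests show: parameter recovery under the
stated noise model, not robustness to every failure mode of real assay data.
A lognormal multiplicative noise option for binding counts is the one
concession to count-like data.

## Worked example

```{r example}
# Simulate a pERK-like experiment around a 32 nM truth and fit it
curve <- gen_dose_response(
  truth = list(bottom = 0, top = 100, pEC50 = -log10(32e-9), hill = 1),
  conc = conc_grid(1e-10, 1e-4, 8), replicates = 3, noise_sd = 0.05,
  seed = 1, ligand = "HTL9936", pathway = "pERK")
fit_4pl(curve)

# Clinical exposure arithmetic: 242 ng/mL plasma Cmax, CSF:plasma ratios
brain_exposure_range(242, mol_weight = 365.5, ratios = c(0.11, 0.30, 0.39))
```

## Problem sizes and runtime

The packaged checks use the sizes the analyses were designed at: 200 seeded
simulations per parameter-recovery criterion (4PL potency, Schild pA2,
bias window, GTPγS efficacy, competition pKi, saturation K~D~, selectivity
ratio), with smaller sweeps (20–40 seeds, 150–200 bootstrap resamples)
inside the per-module unit tests where the acceptance-scale versions
already cover the full design. All of it runs in well under a minute on a
single CPU.

## Known limitations

* One-site binding and monophasic agonist curves only; no biphasic,
  two-site, kinetic-association or allosteric ternary-complex models.
* The operational fit requires at least two ligands per pathway and
  benefits from a full-agonist reference; with none, $E_m$ is anchored to
  the observed maximum and absolute $\tau$ values should not be
  over-interpreted (transduction-coefficient differences remain reliable).
* Schild analysis assumes surmountable equilibrium competition;
  insurmountable or hemi-equilibrium behavior is out of scope.
* The exposure module is ratio arithmetic, not pharmacokinetics: no AUC,
  no compartmental modeling, no allometric scaling.
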