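---
title: "Fluorometric CYP2C19 inhibition screening: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorometric CYP2C19 inhibition screening: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp2c19ddi)
```

## The problem

Proton pump inhibitors (PPIs) are metabolised by, and can inhibit, the
hepatic cytochrome P450 isozyme CYP2C19. Because CYP2C19 also activates
clopidogrel and clears drugs such as diazepam, inhibition by a co-prescribed
PPI is a clinically relevant drug–drug interaction (DDI) mechanism. The
standard early-discovery screen is a fluorometric endpoint assay: a
recombinant CYP2C19 preparation converts a fluorogenic substrate to a
fluorescent product in a 96-well plate; an inhibitor reduces product
formation and hence the fluorescence read at the end of a fixed reaction
window.

`cyp2c19ddi` implements the complete analysis of such a screen:

1. **Quantification** — percent inhibition per well against on-plate
   controls.
2. **Dose–response modelling** — a four-parameter logistic (4PL) fit yielding
   the IC50 with bootstrap uncertainty.
3. **In-vitro-to-in-vivo extrapolation (IVIVE)** — unbound IC50 and the
   Cheng–Prusoff inhibition constant Ki,u.
4. **Risk call** — the basic static model's Cmax,u/Ki,u ratio against the
   regulatory cutoff.
5. **Simulation** — a kinetic plate simulator with known ground truth, so the
   whole chain is testable without wet-lab data.

## Quantification

With `X` the test-well fluorescence, `A` the solvent-control (uninhibited
reaction) mean and `B` the positive-inhibitor (ticlopidine, fully inhibited)
mean:

$$\%I = \left(1 - \frac{X - B}{A - B}\right)\times 100$$

Replicate control wells are averaged at the RFU level before the formula is
applied (the plate-reader convention, and the formula's single-`X` form).
Values outside [0, 100] are **kept**: the fitter needs unclipped responses,
and clipping is purely a display option (`clip = TRUE`).

One interpretation question: assay sheets sometimes label `A` as "solvent
control (fluorescence standard)". The formula requires an
uninhibited-*reaction* reference, so this package treats `A` as the
no-inhibitor reaction control and keeps the fluorescent standard as a
separate `standard` role used only for calibration ([fit_standard_curve()])
and QC. Test-well RFUs are *not* converted to product concentrations before
the inhibition formula — the formula is a ratio of background-anchored
signals, so a linear calibration would cancel anyway; the standard curve is
exposed for QC and optional unit conversion only.

## The dose–response model

Percent inhibition as a function of inhibitor concentration $c$ is modelled
as a 4PL:

$$\%I(c) = bottom + \frac{top - bottom}{1 + (IC_{50}/c)^{h}}$$

Defaults and why:

* **bottom = 0, top = 100 (fixed).** Responses are normalised to the plate's
  own controls, so the asymptotes are known by construction; fixing them
  matches the "normalized response" convention of standard dose–response
  software. `free_asymptotes = TRUE` refits them for QC (e.g. to detect a
  failing positive control).
* **Hill slope free in (0.1, 10].** Unconstrained slopes chase outliers;
  slopes outside this range are not biologically interpretable for a
  single-site reversible inhibitor.
* **Fitting against log10(concentration).** Serial dilutions are geometric;
  log spacing conditions the optimisation and makes the IC50 a location
  parameter.
* **Multi-start.** Five IC50 initial values spanning the tested range, best
  solution by lowest SSE, ties broken by lowest Hill slope (the less steep,
  more conservative curve). The optimiser is bounded least squares
  (`stats::optim`, L-BFGS-B).
* **Convergence is a flag, not an exception.** A fit whose IC50 estimate
  escapes to the boundary of the search box (three decades beyond the tested
  range, as happens with flat responses) or that no clean optimiser run
  reproduces is reported with `converged = FALSE`. Predictions from such fits
  are refused; nothing is silently interpolated.

`fit_ic50()` returns a classed model object with the usual verbs — `print`,
`summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate` — so
it composes with ordinary R workflows.

```{r fit-example}
conc <- rep(50 / 2^(0:7), each = 2)           # 8-point two-fold, duplicates
inh <- 100 * conc / (conc + 2)                # exact hill-1 curve, IC50 = 2
fit <- fit_ic50(conc, inh)
fit
predict_inhibition(fit, 6)                    # closed form: 100*6/(6+2) = 75
```

## IC50 uncertainty: two bootstraps

Published screening tables report IC50 as mean ± spread without saying how
the spread was computed. The package provides two case-resampling bootstraps
and is explicit about what each measures:

* `bootstrap_ic50_sd(fit)` resamples the **dose–response points** (replicate
  wells) and refits. This captures within-plate response noise given the
  plate's normalisation.
* `plate_bootstrap_ic50_sd(wells, compound)` resamples the **raw wells** —
  test wells within each concentration *and* control wells within each
  role — recomputing percent inhibition against the resampled controls
  before every refit.

The distinction matters: every inhibition value on a plate is normalised by
the same control means, so control noise is a *shared* error component. A
points-only bootstrap cannot see it and underestimates the plate-to-plate SD
of the IC50 (in our simulations at 5% CV, by roughly a factor of 2–3). The
plate-level bootstrap tracks the spread observed across independently
simulated plates and is the default used by `fit_plate_ic50(..., n_boot =)`.
Both are deterministic given a seed and restore the caller's RNG state.

## IVIVE and the risk call

The extrapolation chain, with defaults from regulatory guidance for highly
protein-bound drugs:

* **Unbound IC50**: $IC_{50,u} = IC_{50} / f_{u,inc}$ with
  $f_{u,inc} = 0.02$ (fraction unbound in the incubation).
* **Cheng–Prusoff**: $K_{i,u} = IC_{50,u} / (1 + S/K_m)$ for competitive
  inhibition. When substrate kinetics are not resolved, the regulatory
  convention $K_{i,u} = IC_{50,u}/2$ is used — algebraically the
  Cheng–Prusoff value at $S = K_m$. The half convention is the package
  default (`ki_convention = "regulatory_half"`) because it is what published
  screening tables use; the exact form is available with user-supplied `s`
  and `km`. Note the tension: assays are typically run at $S \ll K_m$, where
  Cheng–Prusoff gives $K_{i,u} \approx IC_{50,u}$, yet the /2 convention is
  the one applied in practice. The package implements both and guesses
  neither.
* **Unbound Cmax**: $C_{max,u} = C_{max} \times f_u$ with $f_u = 0.01$;
  micromolar values via the compound's molecular weight
  (`mass_conc_to_molar`).
* **Decision**: flag as potential in vivo inhibitor when
  $C_{max,u}/K_{i,u} \ge 0.02$ (inclusive, in µM/µM). The cutoff is a config
  value, not a constant — guidance revisions move it.

All ratio arithmetic is done in µM. The canonical internal concentration
unit is µM throughout; µg/mL is accepted at the boundary and converted with
packaged molecular weights (omeprazole 345.42, lansoprazole 369.36,
pantoprazole 383.37, rabeprazole 359.44, ilaprazole 366.44, ticlopidine
263.78 g/mol). Mixed-unit division is a classic source of irreproducible
ratio columns in published tables — which is also why **replay mode**
exists: `run_analyze(replay_ic50 = ...)` skips fitting and recomputes the
whole IVIVE chain from stated IC50s, so a published table can be audited
line by line. In the packaged five-PPI table the unbound columns reproduce
exactly, while the published ratio column does not follow from its own
Cmax,u and Ki,u values for any drug; `run_report()` prints computed and
published ratios side by side rather than resolving the discrepancy
silently. The ilaprazole Cmax constant has no primary literature citation
and is back-derived from its published unbound value; it is flagged as such
in `?ppi_constants`.

```{r replay}
rep_tab <- ppi_reported()
res <- run_analyze(replay_ic50 = setNames(rep_tab$ic50_uM, rep_tab$name))
res$assessment[, c("compound", "ic50_uM", "ic50_u_uM", "ki_u_uM", "ratio",
                   "risk_flag")]
```

## The plate simulator

`simulate_plate()` generates complete plates from competitive
Michaelis–Menten kinetics:

$$v = \frac{V_{max} S}{K_m (1 + I/K_i) + S}, \qquad
\text{product} = v \cdot t_{reaction}, \qquad
RFU = (\beta + g \cdot \text{product}) (1 + \varepsilon),\;
\varepsilon \sim N(0, CV)$$

from which the ground-truth half-inhibition point is
$IC_{50} = K_i (1 + S/K_m)$ — so the noiseless inhibition curve is *exactly*
a Hill-slope-1 4PL through the true IC50, giving the fitter a closed-form
oracle.

Defaults, chosen once as realistic assay conditions:

* $K_m = 10$ µM, $S = 1$ µM — honours the low-substrate regime
  ($S \ll K_m$) these screens are run in; neither value is published for the
  kit, so they are declared, not inferred.
* $V_{max} = 1100$ nM/min, gain 1 RFU/nM, background 50 RFU, 10-min
  reaction — an uninhibited window of ~1000 RFU over background, a typical
  mid-gain plate-reader setting.
* **Noise: multiplicative Gaussian, CV 5%.** Plate-reader error scales with
  signal; 5% is a routine between-well CV for mix-and-read fluorescence.
  Noise is drawn per well in row-major order (plate, row, column), so one
  seed fixes the entire table bit-for-bit.
* **Positive control at zero residual activity** — ticlopidine treated as a
  full inhibitor, so `B` fluctuates around background.
* **Layout**: standards columns 1–2 (two-fold from 500 nM, rows A–G; buffer
  blanks H1/H2, following the kit's calibration scheme), up to four
  compounds per plate in duplicate column pairs (8-point series down the
  rows), solvent controls in column 11 and positive controls in column 12
  (rows A–D). The calibration column is prescribed by the kit; the rest of
  the map is this package's own choice. The default test series is 8-point
  two-fold from 50 µM; the narrow 0.8–6.4 µg/mL range quoted for PPI screens
  corresponds to `build_dilution_series(6.4, 2, 4, unit = "ug/mL")`.

What the simulator deliberately does **not** emulate: substrate depletion
(accumulation is linear over the 10-min window), optical cross-talk and
edge effects, inner-filter/quenching artefacts, time-dependent
(mechanism-based) inactivation, and NADPH-regeneration kinetics. Passing
tests therefore demonstrate that the *analysis* chain is correct and
well-calibrated under idealised reversible-inhibition conditions — not that
it is robust to every plate pathology of real screens.

## Validation design and problem sizes

The test suite validates the chain at three levels:

* **Exact**: unbound-correction and unit arithmetic against a published
  five-PPI summary table (printed-precision agreement; µM conversions to
  within one unit in the last printed digit, since the printed values are
  3-significant-figure roundings).
* **Oracle equivalence**: noiseless simulator curves equal
  $100\,i/(i + IC_{50})$ analytically, and refitting recovers the true IC50
  to well under 0.1% for IC50 ∈ {0.5, 1.41, 6.62} µM.
* **Stochastic calibration**: 50 simulated plates at CV 5% (8-point two-fold
  series, duplicates) give a median relative IC50 error under 10%, and the
  plate-level bootstrap SD (500 resamples) falls within a factor of 2 of the
  SD across a 200-plate Monte-Carlo oracle. These sizes make the whole suite
  run in well under a minute while leaving the stochastic assertions far
  from their pass/fail boundaries.

## Configuration and orchestration

`pipeline_config()` gathers the assumption set (fu values, Ki convention,
threshold, fit options, seed); YAML config files are supported via
`read_config()` (unknown keys are an error, so a typo cannot silently revert
a regulatory assumption). A thin command-line front end with `simulate`,
`analyze` and `report` subcommands ships in
`system.file("scripts", "cyp2c19-pipeline.R", package = "cyp2c19ddi")`.
Every run carries a provenance block (package version, seed, config
fingerprint) sufficient to reproduce deterministic stages exactly.

## Known limitations

* The basic static model is a *screen*: a ratio below the cutoff excludes
  reversible-inhibition risk under its assumptions; it does not address
  mechanism-based inactivation, gut-wall interaction terms, fraction
  metabolised, or PBPK-level questions.
* The /2 Ki convention and the fixed fu values are regulatory conventions,
  not measurements; compound-specific fu,inc and substrate kinetics should
  replace them when available.
* IC50s from a single plate carry ~10–15% sampling error at 5% CV; ranking
  compounds whose IC50s differ by less than that requires replicate plates.
* The simulator's idealisations listed above.
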