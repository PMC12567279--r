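---
title: "Modeling escitalopram exposure across pregnancy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling escitalopram exposure across pregnancy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escipbpk)
```

# The problem

Escitalopram, a CYP2C19-cleared SSRI, shows substantial pharmacokinetic
change during pregnancy: enzyme induction, increased cardiac output and
glomerular filtration, plasma-volume expansion and reduced binding-protein
concentrations all push maternal exposure down with advancing gestation,
while the drug crosses the placenta freely enough that the fetus sees a
large fraction of the maternal concentration. `escipbpk` implements a
whole-body physiologically based pharmacokinetic (PBPK) model that makes
these mechanisms explicit so that maternal and fetal exposure can be
simulated for any gestational week, dose, and CYP2C19 phenotype, and
dosing regimens can be assessed against the drug's therapeutic window.

# Model structure

## Maternal whole-body model

The maternal model is a perfusion-limited whole-body PBPK system with 13
compartments (adipose, bone, brain, gut, heart, kidney, liver, lung,
muscle, skin, spleen, rest-of-body, plasma). For each tissue $t$ with
blood flow $Q_t$ (L/h), volume $V_t$ (L) and tissue-to-plasma partition
coefficient $K_{p,t}$,

$$\frac{dA_t}{dt} = Q_t\,R_{bp}\left(C_p - \frac{C_t}{K_{p,t}}\right),$$

with $R_{bp}$ the blood-to-plasma ratio, $C_p$ the plasma concentration
and $C_t = A_t/V_t$. Gut and spleen drain into the liver; the lung
receives the full cardiac output; the systemic flows sum to cardiac output
by construction (they are stored as fractions and scaled together).

Oral absorption is first order from a depot with rate constant $k_a$; the
amount reaching the liver is multiplied by the fraction absorbed $f_a$ and
the gut-wall availability of the "Qgut" model,

$$F_g = \frac{Q_{gut}}{Q_{gut} + fu_{gut}\,CLu_{int,gut}},$$

with the gut-wall intrinsic clearance scaled up from the CYP3A4 per-pmol
clearance and a fixed total gut CYP3A4 amount (fixture: 70 nmol). With the
packaged parameters $F_g \approx 0.99$ — a fact with consequences for
identifiability, discussed below.

Hepatic elimination is well stirred: the liver compartment eliminates at
rate $fu_p\,CLu_{int}\,C_{liver}/K_{p,liver}$, which at steady state is
algebraically identical to the familiar
$CL_h = Q_h\,fu_B\,CLu_{int}/(Q_h + fu_B\,CLu_{int})$ on a blood basis
(with $fu_B = fu_p/R_{bp}$); the test suite asserts this equivalence
against the analytic closed form. The whole-liver unbound intrinsic
clearance is scaled up per isoform:

$$CLu_{int} = \sum_{i \in \{2C19,\,2D6,\,3A4\}} CL_{int,i}\cdot
  A_i \cdot \mathrm{MPPGL} \cdot W_{liver} \cdot m_i^{preg} \cdot m_i^{phen},$$

where $A_i$ is the abundance (pmol/mg microsomal protein),
$m_i^{preg}$ the gestational activity multiplier and $m_i^{phen}$ the
phenotype multiplier. Renal elimination is the adult renal clearance
scaled by the GFR ratio to baseline.

## Partition coefficients

Tissue partitioning uses the mechanistic equations for moderate-to-strong
monoprotic bases (pKa 9.5 here): ionization-partitioned tissue water,
neutral-lipid/phospholipid partitioning, and electrostatic association of
the ionized base with tissue acidic phospholipids. The
acidic-phospholipid association constant is back-calculated from
blood-cell binding, i.e. from the measured blood-to-plasma ratio and
hematocrit, so no drug-specific tissue binding input is needed. The
composition table (water fractions, lipid fractions, acidic phospholipid
per tissue) ships as a versioned fixture. Every predicted $K_p$ is
multiplied by the empirical scalar from the compound file (0.92). The
implied steady-state volume of distribution, including the erythrocyte
term derived from the blood-to-plasma ratio, is about 10.2 L/kg — within
25% of the reference prediction of 13.5 L/kg, which is the agreement one
can expect given that the composition table and baseline organ weights are
surrogates for a proprietary population library.

## Gestational scaling

Every pregnancy trajectory is a polynomial multiplier on the
week-0 baseline,

$$x(GW) = x_0\,(1 + b_1 GW + b_2 GW^2 + b_3 GW^3 + b_4 GW^4).$$

CYP2D6 ($b_1 = 0.0163$, $b_2 = 0.0009$) and CYP3A4 ($b_1 = 0.0129$,
$b_2 = 0.0005$) use published induction coefficients; CYP2C19 activity is
held constant (all coefficients zero). The remaining trajectories are
package fixtures in the same polynomial form, chosen from the
pregnancy-physiology literature and overridable through
`build_physiology(scaling = ...)`:

| trajectory | $b_1$ | $b_2$ | value at week 40 |
|---|---|---|---|
| cardiac output | 0.02 | -0.0003 | 1.32 |
| GFR | 0.035 | -0.0006 | 1.44 |
| binding protein (AGP) | -0.0045 | 0 | 0.82 |
| plasma volume | 0 | 0.00028 | 1.45 |

The binding protein is taken to be alpha-1 acid glycoprotein, the
principal binder of moderately lipophilic bases; its decline raises the
unbound fraction through
$fu' = 1/(1 + \frac{1-fu}{fu}\,r)$ with $r$ the protein concentration
ratio. Fetal weight follows $3.7\,(GW/40)^{3.4}$ kg and amniotic volume
$0.75\,(GW/40)^2$ L, both anchored to the term reference values (3.7 kg;
750 mL/day swallowed at term).

## Fetoplacental unit

From gestational week 15 the model adds a small placental tissue node
(0.5 L) between two permeability barriers with clearances $CL_{PDM}$
(maternal side) and $CL_{PDF}$ (fetal side), both 0.80902 L/h for
escitalopram, a fetal plasma compartment, and an amniotic fluid
compartment. Transfer across both barriers is driven by *unbound*
concentrations — the barrier basis is not stated by simulator
documentation, and the unbound basis is this package's documented choice,
because in a linear conservative exchange a sub-unity total-concentration
cord-to-maternal ratio can only arise from binding asymmetry. Fetal
elimination is renal (per-kg value from the adult clearance scaled by the
fetal/adult GFR ratio, times current fetal weight) into amniotic fluid,
and swallowing (per-kg value from the term amniotic ingestion volume)
returns drug to fetal plasma, fully reabsorbed. The unit's only exit is
back-transfer to the mother, so its mass balance is closed.

At a true steady state the fetal:maternal total-concentration ratio of
this structure is exactly $fu_m/fu_f$; with once-daily dosing the
time-averaged ratio over the last interval is close to it. With the
maternal binding-protein ratio 0.82 at term and the fetal ratio fixture
0.37 of the maternal baseline, $fu_m = 0.489$, $fu_f = 0.680$, predicting
a ratio of 0.72 — the simulation reports 0.719, against clinical
observations of about 0.7. The trough (delivery-time) ratio, reported
alongside, is higher (~0.99) because the fetal compartment lags maternal
fluctuations; clinical cord samples taken at delivery, hours after the
last dose, sit between the two.

# CYP2C19 phenotypes

Phenotypes scale the CYP2C19 intrinsic clearance with multipliers
UM 1.3, NM 1.0, IM 0.75, PM 0.6, and default Caucasian frequencies
{PM 0.02, IM 0.26, NM 0.60, UM 0.12}. The multipliers were calibrated
against the simulated qualification quantities — the IM/NM steady-state
AUC ratio (~1.12) and the per-phenotype trough-concentration ranges at 10
and 20 mg — not against the literature exposure folds (3.3-fold in PM),
for a structural reason the calibration table in
`analysis/04_phenotypes.R` makes explicit: with the packaged clearances,
CYP2C19 carries ~64% of hepatic intrinsic clearance, so even complete
loss of CYP2C19 activity caps the AUC fold at ~2.2 (CYP2D6, CYP3A4 and
renal clearance persist). Literature folds of 3.3 are unreachable in this
structure; a multiplier small enough to chase them would push poor
metabolizers' troughs far above every published simulated value. Virtual
individuals add median-preserving log-normal variability (CVs: CLint 35%,
$k_a$ 25%, Kp scalar 20%, $fu$ 15% — documented surrogates, the source
material prints no variability settings).

# Numerical design

The system is linear and time-invariant at fixed gestational week, which
the implementation exploits twice:

* **Unit-dose scaling.** Every simulation runs at 1 mg and rescales, so
  dose proportionality is exact by construction, not merely to solver
  tolerance.
* **Two solution paths.** The default integrator is `deSolve::lsoda`
  (rtol 1e-8, atol 1e-10, output grid 0.1 h, repeated doses as
  depot-replenishment events). For population-scale work,
  `sim_settings(solver = "linear")` assembles the system matrix
  column-by-column *from the same right-hand side*, solves it exactly by
  eigendecomposition, and superposes doses — about fifty-fold faster and
  exact. The suite asserts agreement of the two paths below 1e-6; mass
  balance (dose = body content + cumulative eliminated + pre-systemic
  loss) is checked after every solve.

One quadrature caveat: trapezoidal AUC on the output grid is accurate for
oral profiles but not for an intravenous bolus, whose initial distribution
spike decays faster than any reasonable grid. Analytic AUC checks
therefore read the plasma AUC from the renal elimination accumulator
($A_{ren}(\infty) = CL_R \cdot AUC$), which is quadrature-free.

PK metrics (Cmax, Tmax, interval AUC, trough, average) are computed on
the final dosing interval of the dense output. Degenerate inputs are
rejected loudly: negative gestational weeks, weeks beyond 40, fetal
simulation before week 15, unknown physiology overrides, non-positive
observations in fold-error statistics.

# Sensitivity screening

Morris elementary-effects screening runs `r` randomized one-at-a-time
trajectories on a four-level grid, reporting $\mu^*$ (mean absolute
elementary effect) and $\sigma$ per parameter and output. The screened
set contains nine drug-specific parameters: the absorption inputs
($f_a$, $k_a$, $fu_{gut}$, $Q_{gut}$), the distribution scalar
($K_p$ scalar), and the elimination inputs (three isoform CLints and
$CL_R$), each over ±50% of its default. The measured binding constants
($fu_p$, B/P) are deliberately excluded: the elasticity of oral AUC to
$fu_p$ equals the hepatic share of clearance (~0.85), so including it
with a ±50% range would mechanically place it at rank 2 for AUC and
drown the clearance ranking the screen is meant to expose. Outputs are
single-dose (20 mg) Cmax and extrapolated AUC — single-dose Cmax is
distribution/absorption-dominated (Kp scalar, $f_a$, $k_a$), whereas
steady-state Cmax would be clearance-dominated; the single-dose choice is
what makes the two output rankings informative about different parts of
the model.

# Parameter estimation and identifiability

`fit_parameters()` minimizes $\sum_i w_i (y_i - \hat y_i)^2$ with
$w_i = 1/y_i^2$ (proportional error; uniform and $1/y$ weights are
selectable) by Nelder-Mead in log-parameter space — positivity for free —
with restarts drawn log-uniformly within bounds from the seed, and a
quadratic box penalty keeping flat directions inside the bounds.

On noise-free synthetic data all three fitted parameters ($k_a$,
$Q_{gut}$, Kp scalar) are recovered to well under 2%. Under 15%
proportional noise, $k_a$ and the Kp scalar recover with median absolute
relative errors of roughly 5% and 7% over 20 replicates, but $Q_{gut}$
does not, and cannot: its only effect is through $F_g \approx 0.99$, so
the relative sensitivity of any concentration to $Q_{gut}$ is
$1 - F_g \approx 1\%$; recovering it to 15% would need data precise to
~0.2%. This is a structural identifiability limit of the parameter given
this compound's negligible gut extraction, not an optimizer failure — the
corresponding accuracy test is expected to flag it, and the fitted
$Q_{gut}$ value should be read as "anything within bounds fits equally
well". The same caveat applies to any estimate of $Q_{gut}$ for this drug
obtained from plasma data alone.

# Synthetic observations

`generate_observed()` emulates the sparse steady-state sampling of
clinical lactation/delivery studies: per subject it draws individual
parameters, simulates the truth model, samples at a trough-heavy grid
(default 1, 2, 4, 6, 12, 24 h after the last dose), and multiplies by
median-preserving log-normal residual error. What it deliberately does
*not* emulate: assay error structure at the quantification limit,
non-adherence, co-medication, comorbidity, or time-varying physiology
within a dosing interval. Closure tests (the model verifies against its
own synthetic data; the 5th-95th band covers ~90% of fresh draws from the
same population) therefore demonstrate internal consistency of the
pipeline, not clinical predictive performance.

# Problem sizes and runtime choices

The packaged analyses use: 10-day once-daily regimens (steady state is
reached by day 7, asserted in the suite); populations of 10x10 for
verification and 20x20 per cell for dose assessment; Morris with r = 20
trajectories; estimation with 40-100 restarts in the analysis driver and
fewer in the replicated-recovery tests, where the linear solution path
makes each model evaluation ~4 ms. These sizes were chosen so the whole
analysis reruns in minutes on a laptop while keeping Monte-Carlo error
well inside every tolerance used.

# Known limitations

* Baseline organ volumes/flows, enzyme abundances and the tissue
  composition table are documented surrogates for proprietary population
  libraries; absolute concentrations are expected to sit within tens of
  percent of the reference predictions, and qualification focuses on
  relative quantities (percent decline with gestation, concentration
  ratios, rankings).
* No metabolite kinetics (the demethylated metabolites are essentially
  inactive), no saturable elimination, no transporters, no fetal CYP
  phenotypes, and CYP2C19 activity is held constant across gestation.
* The placental barrier clearances are inputs, not predictions from
  molecular properties.
* The cord-to-maternal ratio is reported as a time-averaged and a trough
  quantity; clinical delivery sampling corresponds to neither exactly.
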