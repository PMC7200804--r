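---
title: "Circadian population pharmacokinetics of tacrolimus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian population pharmacokinetics of tacrolimus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronotac)
```

# The problem

Oral tacrolimus in paediatric renal-transplant recipients has a narrow
therapeutic index, large inter-individual variability, and a
well-documented day/night pattern in its disposition: exposure after the
morning dose is consistently higher than after the evening dose.
`chronotac` implements two population pharmacokinetic models of
whole-blood tacrolimus that make that circadian behaviour explicit, a
FOCE estimation layer, boundary-constrained individual adaptation for
formulation conversion (twice-daily fast release to once-daily prolonged
release), an evaluation battery, and a virtual paediatric cohort
generator so that every stage of the pipeline runs without clinical
data.

# The circadian kernel

Clearance-like and absorption-like parameters are modulated by a 24-h
periodic waveform $f_w(t)$ that equals 1 during the diurnal phase,
descends linearly over two hours to a plateau $r_{chr} \le 1$ during the
nocturnal phase, and returns over two hours, with breakpoints at
$t_1,\dots,t_4 = 10, 12, 22, 24$ h.  A phase parameter $t_{chr}$ shifts
the diurnal onset relative to the dataset's morning reference:

$$Cl_{chr}(t) = Cl \cdot f_w(t - t_{chr}), \qquad
  K_{a,chr}(t) = K_a \cdot f_w(t - t_{chr}).$$

Only the amplitude $r_{chr}$ and phase $t_{chr}$ carry inter-individual
variability; the breakpoints fix the shape.  This piecewise-linear
kernel is the simplest waveform consistent with the reported diurnal
physiology; no harmonic (cosinor) alternative is provided.

Model time is in hours with $t = 0$ at a morning reference (08:30 by
convention, `reference_clock_offset`); the first hospital admission sits
at $t = 48$ h so that two days of run-in dosing precede the first
intensive sampling day.

# The compartmental model (PK/CAT3)

Two-compartment disposition with a three-segment
compartmental-absorption-and-transit gut: a zero-order dose input of
duration `FDT` (0.5 h per formulation by default) fills the stomach;
drug transits stomach → three small-intestine segments → colon at rate
$k_t = 1/MTT$ per region; each intestinal segment is absorbed into the
central compartment at the chronomodulated rate
$k_{ta} f_w(t - t_{chr})$; nothing is absorbed from stomach or colon.
Elimination is linear from the central compartment at
$Cl \cdot f_w(t-t_{chr})$, with inter-compartmental clearance $Cl_d$
between central ($V_c$) and peripheral ($V_p$) volumes.

The absorption constant is reported in fluid-concentration units
($K_a$, ml/h), so the operative rate constant is
$k_{ta} = K_a / V_{cat,si}$.  Only the ratio is identifiable;
$V_{cat,si}$ is therefore a fixed structural constant, never estimated.
Its default (0.065 L) was calibrated once, together with the PBPK
liberation-loss constant below, so that the shipped population means
reproduce the published day-1 bioavailability and exposure of the study
cohort (F ≈ 18.9% and AUC$_{24}$ ≈ 200 ng/ml·h at cohort-typical
dosing); the published source defers the gut fluid volumes to its
supplement.

Running bioavailability is accumulated during simulation per the
clearance identity

$$F(t)\int_0^t D_f\,\mathrm{d}t = \int_0^t Cl_{chr}(t)\,C_c(t)\,\mathrm{d}t,$$

and every simulation carries a mass ledger (dosed, in transit, absorbed,
eliminated, colon loss) whose closure is checked to solver precision.

# The reduced PBPK model

Six regions: gut lumen and gut tissue, liver, kidney, fat, others, and
whole blood.  Each dose is liberated into the lumen by a zero-order
process over the formulation's liberation time `LibT` (minutes; 100 for
fast release), competing with a first-order loss
$K_{elib}(LibT) = K_{elib}^{ref} \cdot LibT/100$ — slower liberation
leaves more drug stranded in transit — and chronomodulated first-order
absorption $K_{abs} f_w$ into gut tissue.  Perfused tissues equilibrate
with venous blood through Poulin–Theil tissue:plasma partition
coefficients computed from neutral-lipid/phospholipid/water fractions
(packaged, overridable tables) and a lipophilicity descriptor
(log P = 3.3, a drug-database constant).  Hepatic elimination acts on
the unbound plasma concentration of the liver venous outflow:

$$\text{elimination rate} = V_l \, Cl_{ih} \, f_w(t - t_{chr}) \, fu_p
  \, C_{p,vl},$$

with $Cl_{ih}$ the intrinsic clearance per litre of liver and
$fu_p = 0.012$.

**Blood-pool convention.**  The measured quantity is whole blood.  The
model tracks a plasma-referenced concentration $C_p$ and adds the
saturable red-blood-cell pool at equilibrium,
$C_b = C_p + Hct \cdot B_{max} C_p/(K_d + C_p)$.  Two observations force
this convention: with the shipped $B_{max} = 11.0$ and $K_d = 1.6$ µg/L
the plasma-referenced concentrations (3–10 µg/L at therapeutic levels)
actually span $K_d$, making the binding constants identifiable, and the
implied whole-blood clearance is consistent with the compartmental
model's ~3 L/h effective clearance on the same population.  Scaling the
free side additionally by $fu_p$ (i.e. treating $C_p$ as free rather
than plasma-total) would put free concentrations 10× below $K_d$
everywhere and inflate clearance several-fold.  The standalone
equilibrium calculator `blood_partition()` exposes the fuller mixing
algebra (plasma total $= C_u/fu_p$) for use as a reference computation.
An explicitly membrane-limited gut/blood exchange is collapsed to its
equilibrium limit; the permeability–surface-area form added nothing at
the time resolution of the data.

Physiology scales from a packaged reference table: volumes as fixed
fractions of body weight (liver 2.6%, kidney 0.44%, gut 1.7%, fat 19%
+5 points for females, blood 7.7%, remainder to "others"), flows as
fractions of allometric cardiac output $336 (BW/70)^{0.75}$ L/h (gut
15.5%, hepatic artery 6.5%, kidney 19%, fat 5%).  Haematocrit is a
subject covariate.  Renal excretion is negligible and not modelled.

$K_{elib}^{ref}$ (10 1/h at the 100-min reference) is the second
calibrated structural constant: it sets the typical day-1
bioavailability to the published 15.0 ± 1.6%.  The Monte Carlo exposure
targets were *not* used in either calibration and serve as an
out-of-sample check.

# Numerical treatment

Both right-hand sides are compiled C evaluated by `deSolve::lsoda`
(default tolerances: relative 1e-8, absolute 1e-10 mg).  Zero-order
inputs make the vector field discontinuous, so reported simulations
restart the solver at every dose-window edge; the estimation loops use
a single-call fast path with the edges inserted as output points, which
agrees with the restarted integration to ~1e-6 relative and is several
times faster.  Mass-balance closure (dosed = retained + eliminated +
lost) is asserted to 1e-6 relative in the test suite and holds to
~1e-15 at default tolerances.

# Population estimation

Inter-individual variability is exponential,
$\theta_i = \theta e^{\eta_i}$, $\eta \sim N(0, \Omega)$ with diagonal
$\Omega$ (no printed covariances to honour, and 21 subjects cannot
support a full block).  The residual model is additive on
log-concentration by default (variance $\omega_r^2$), with a
proportional alternative evaluated under FOCE-I (residual variance
recomputed at the conditional estimates).  Observations flagged below
the 2 ng/ml quantification limit are excluded from all objectives — the
source protocol reports dilution above the upper limit, so no upper
censoring is needed, and no likelihood-based BLQ treatment is described;
exclusion is the declared assumption.

The FOCE objective finds each subject's empirical Bayes mode by a
damped Gauss–Newton search (warm-started across outer iterations, model
Jacobian refreshed only on large steps), linearises the model there and
accumulates

$$-2\ell_i = n_i\log 2\pi + \log|V_i| + r_i' V_i^{-1} r_i,\quad
  V_i = G_i \Omega G_i' + \Sigma_i,\quad
  r_i = y_i - f_i(\hat\eta_i) + G_i\hat\eta_i,$$

which is exact for models linear in $\eta$ — the property the test
suite verifies against a closed-form linear-Gaussian oracle to 1e-6.
The outer optimiser is Nelder–Mead on log-transformed fixed effects and
variances; relative standard errors come from the numerical Hessian at
the optimum (with the inner warm starts frozen so the finite differences
see a smooth function), reported as $SE(\theta)/\theta$ and
$SE(\omega^2)/2\omega^2$.  The circadian-phase variance is held fixed
during estimation by default: its reported uncertainty suggests it was
not estimated, and a `omega_fixed` switch exposes the choice.
Inter-occasion variability is deliberately absent.

Covariate links are multiplicative (linear, power/exponential or
categorical forms, reference at the covariate median).  Forward stepwise
selection accepts a candidate when the objective drops by at least 3.84
($\chi^2_1$, 5%), or by at least 75% of that threshold together with a
≥10% reduction of the linked parameter's inter-individual CV — the
published selection accepted the body-surface-area/distribution-clearance
link at an objective drop of 2.95 under exactly such a near-threshold
rule, and the shipped PK population includes that link
(exponent 1.17, reference 1.30 m²).

Finite-sample behaviour: at 21 subjects the conditional estimator
carries a few-percent upward bias on the absorption parameters (≈+8% on
$K_a$); the recovery tests therefore check that the bias stays within
two empirical standard errors of one refit rather than demanding
asymptotic unbiasedness.

# Individual adaptation

After the 1:1 conversion to once-daily prolonged release, two
techniques re-align a fitted subject:

* **Boundary-constrained Bayesian MAP**: re-optimises the random effects
  of population parameters against the new observations plus the
  population prior, with each increment $\Delta\eta$ box-constrained
  either by an absolute bound $B$ or by the weighted bound
  $W_b \cdot \max(|\eta_0|, \eta_m)$.  The published inequality prints a
  *minimum* of the previous state and the reference $\eta_m$, but that
  box has zero width at the typical starting state $\eta_0 = 0$ (and for
  any negative $\eta_0$ under a signed reading); since $\eta_m$ is
  described as the *minimal* value defining the boundary, it is
  implemented as a floor.  Structural constants (LibT, FDT, $K_{abs}$)
  cannot be Bayes-adapted — they have no prior.
* **Weighted least squares** on log concentrations,
  $F_{wse} = W \sum_k (\ln C_b(t_k) - \ln \hat C_b(t_k))^2$, which may
  free structural constants as well.  The optimum location is invariant
  to $W$ (default 1).

Adaptations act from their change time onward through a per-subject
parameter timeline, so multi-stage procedures preserve earlier
corrections.  Procedure 1 first corrects the day-8 trough with a single
release-rate parameter (LibT for the PBPK model; the compartmental FDT
has little leverage on the release rate, mirroring the published
finding) applied at the conversion, then refines the remaining day-8
samples at the start of day 8.  Procedure 2 uses all day-8 samples with
a single change at the conversion.  Reported outputs per subject:
parameter increments, post-adaptation log-scale RMSE, model-minus-NCA
AUC$_{24}$, and the day-8 vs day-1 bioavailability change.

Identifiability: with 13 day-8 samples the three PBPK mechanisms
(liberation time, absorption rate, intrinsic clearance) trade off along
a near-flat ridge when freed jointly; the recovery tests isolate one
mechanism at a time, which is precisely the rationale for the two-stage
clinical procedure.

# Evaluation battery

* **NCA**: log-trapezoidal AUC (arithmetic fallback at equal
  concentrations), exact on log-linear profiles.
* **RMSE$_c$**: root-mean-square error of log concentrations.
* **pcVPC**: prediction correction by the bin-median population
  prediction over the subject's population prediction, one bin per
  protocol sampling time, 500 simulated replicas by default, 95%
  confidence bands of the 5/50/95 percentiles, stratified at
  dose/BSA = 0.9 mg/m².
* **Monte Carlo exposure**: per dose level, virtual subjects are drawn
  from the demographic model and the fitted population, dosed twice
  daily for 36 h from drug-free initial conditions, and the final 24 h
  integrated; mean ± SD of AUC$_{24}$, bioavailability and time above a
  20 ng/ml tolerability threshold are reported.  Dose levels are mg/kg;
  by default the administered amount is the level scaled by the 60-kg
  reference (0.042 mg/kg → 2.5 mg per administration), the reading of
  the published "normalised" dose levels that reproduces both published
  exposure means; per-kg administration is available as an option.
  Whether 600 runs means per dose level or in total is not stated in
  the source; the default is 600 per level.

# The virtual cohort

Demographics are truncated normals at the published summaries (age
12.9 ± 4.17 y on [4, 17]; weight 42.85 ± 15.42 kg on [15.1, 63.8];
height 143.4 ± 18.16 cm on [105, 168]; 57% male), with a 0.7
weight–height copula correlation so derived BSA values stay realistic —
the source gives no joint distribution.  Haematocrit is uniform on
0.33–0.45 (a paediatric range; not reported).  The protocol skeleton is
the study's: 48 h of run-in q12h fast-release dosing, day-1 sampling at
the 18 published offsets, conversion to once-daily prolonged release at
1:1 daily dose on day 2, and day-8 sampling at the 13 published offsets;
assay limits 2–30 ng/ml with values above 30 retained (dilution).

**Dose titration.**  The enrolled patients were stable, TDM-titrated
recipients (dose and concentration variation below 20% for 30 days).  A
fixed mg/kg rule reproduces neither the level nor the spread of their
exposure — it yields a tail-inflated day-1 AUC$_{24}$ (mean ≈ 270,
CV ≈ 40%) because dose and individual clearance are uncorrelated.  The
generator therefore emulates titration: each subject's per-administration
amount is rescaled and rounded to 0.5-mg strengths until the predicted
day-1 AUC$_{24}$ approaches 200 ng/ml·h (the centre of the published
cohort exposure, inside the 180–350 paediatric target window).  This
reproduces the published day-1 exposure distribution (≈196 ± 15–30
against 201.48 ± 39.27 observed).

**Conversion drift.**  The drift specification injects, at the start of
day 2, an additive LibT shift (default +176 ± 225.4 min, the published
single-parameter conversion estimate), an FDT analogue for the
compartmental model (+0.34 ± 0.50 h), and mean-zero week-scale
intra-patient shifts of clearance (~15% CV) and absorption (~25% CV) —
magnitudes typical of stable tacrolimus patients; the published
multi-parameter adaptation increments are too collinear to serve as
generating values.

**What the generator does not emulate.**  Real day-8 exposure fell to
177.1 ± 42.3 ng/ml·h after conversion.  Both circadian models predict a
bioavailability *gain* under once-daily morning dosing (all absorption
moves into the diurnal window), the same over-prediction the source
reports for its unadapted models on day 8; in the synthetic world the
injected liberation shift only partly offsets it, so synthetic day-8
exposure runs ~15–30% above the clinical value, with wide seed-to-seed
spread inherited from the ±225-min shift dispersion.  Tests that pass on
synthetic day-8 data therefore validate the adaptation *machinery*
(shift recovery, error reduction), not the clinical day-8 exposure
level.  Likewise, passing recovery tests show estimator self-consistency
in the model's own world, not correctness on real patients: real data
carry assay artefacts, food effects, adherence gaps and model
misspecification that no self-generated cohort exhibits.

# Problem sizes used by the shipped tests

The test suite regenerates everything from code: 21-subject cohorts for
the fitting checks; 20-seed batteries for parameter recovery (fixed
effects re-estimated with variances held at their generating values),
adaptation-shift recovery (4-subject cohorts per seed, one mechanism at
a time) and pcVPC self-consistency (90 replicas per seed); 600-run
Monte Carlo exposure per model.  These sizes were chosen so the whole
battery completes in minutes while leaving the Monte Carlo standard
errors well below the tolerances they support.

# Known limitations

* The gut fluid volume and liberation-loss reference are calibrated
  constants (see above); the exact values used by the source live in
  its unpublished supplement, and other (volume, rate) pairs with the
  same products are observationally equivalent.
* The hepatic driving-concentration convention is a declared
  interpretation; a well-stirred variant driving on unbound venous
  blood is observationally close but shifts the clearance scale.
* FOCE carries finite-sample bias at 21 subjects (documented above).
* No inter-occasion variability, no enterohepatic recirculation, no
  lag time, no colon absorption, no CYP genotype or drug–drug
  interaction covariates, no renal excretion.
* The pcVPC is computed, not drawn; plotting is left to the caller
  (`tac_vpc` objects are plain data frames).
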