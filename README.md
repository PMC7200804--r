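# chronotac

Circadian population pharmacokinetic models of oral tacrolimus in
paediatric renal-transplant recipients.

Tacrolimus has a narrow therapeutic index, large between-patient
variability, and a pronounced day/night pattern: exposure after the
morning dose exceeds exposure after the evening dose.  `chronotac`
models that behaviour explicitly.  Clearance-like and absorption-like
parameters are modulated by a 24-h periodic waveform

    f_w(t) = 1 on the diurnal phase, r_chr on the nocturnal phase,
             2-h linear ramps between (breakpoints 10/12/22/24 h)

so that, e.g., `Cl_chr(t) = Cl · f_w(t − t_chr)`.  Two structural models
share the kernel:

* **PK/CAT3** — two-compartment disposition with a three-segment
  compartmental-absorption-and-transit gut (zero-order dose input of
  duration FDT into the stomach, serial transit at `k_t = 1/MTT`,
  chronomodulated first-order absorption from the small-intestine
  segments only).
* **Reduced PBPK** — gut lumen (zero-order liberation over `LibT`
  minutes, competing liberation-dependent loss
  `K_elib(LibT) = K_elib(100)·LibT/100`, chronomodulated absorption),
  gut tissue, flow-limited liver/kidney/fat/others with Poulin–Theil
  partition coefficients, saturable red-blood-cell binding
  (`B_max`, `K_d`) in whole blood, and hepatic elimination
  `V_l · Cl_ih · f_w(t − t_chr) · fu_p · C_p,vl`.

Around the models: FOCE population estimation with exponential
inter-individual variability (`theta_i = theta·e^eta`), covariate links
and forward stepwise selection; boundary-constrained Bayesian MAP and
weighted-least-squares individual adaptation with per-subject parameter
timelines (for the fast-release → prolonged-release conversion);
log-trapezoidal NCA, prediction-corrected VPCs and Monte Carlo exposure
simulation; and a virtual paediatric cohort generator (published
demographics, two-phase protocol, emulated dose titration, injectable
conversion drift) so the entire pipeline runs without clinical data.
Both ODE right-hand sides are compiled C integrated by `deSolve`, with
a machine-precision mass ledger and a running absolute-bioavailability
accumulator `F(t)` on every simulation.

Shipped parameter defaults are the fitted paediatric population
estimates (e.g. `Cl` 5.41 L/h, `Ka` 13.8 ml/h, `MTT` 0.72 h,
`r_chr` 0.29 for the PK model; `Cl_ih` 956.6 1/h, `B_max` 11.0 µg/L,
`K_d` 1.6 µg/L, `r_chr` 0.16 for the PBPK model).

## A worked example

Simulate a typical 42.85-kg subject on 2 mg twice daily (48 h of run-in,
then the intensive monitoring day):

```r
library(chronotac)

s <- subject("P01", sex = "M", age = 12.9, body_weight = 42.85,
             height = 143.4, haematocrit = 0.35,
             doses = data.frame(time = seq(0, 60, by = 12), amt = 2.0,
                                formulation = "fast_release"))
sim <- simulate_pk(s, pk_params(), times = seq(0, 72, 0.5))
print(sim)
#> pk simulation: 145 time points, F(end) = 19.0%, mass balance error 4.44e-16

day1 <- sim[sim$time >= 48, ]
sprintf("day-1 trough %.1f ng/ml, peak %.1f ng/ml",
        day1$conc[1], max(day1$conc))
#> [1] "day-1 trough 8.0 ng/ml, peak 14.7 ng/ml"
auc_logtrap(day1$time, day1$conc)
#> [1] 250.3653
round(attr(sim, "ledger"), 4)
#>             input          absorbed        eliminated             colon
#>           12.0000            2.8186            2.2766            9.1813
#>             F_end balance_rel_error
#>            0.1897            0.0000
```

The ledger reads: of 12 mg dosed, 2.82 mg was absorbed, 2.28 mg already
eliminated, 9.18 mg lost to the colon; the running bioavailability at
72 h is 19.0% (the reported population value was 18.8 ± 9.7%).  Note the
circadian signature in the profile: the evening-dose peak is much
flatter than the morning one (nocturnal absorption), while overnight
concentrations decay slowly (nocturnal clearance at `r_chr·Cl`).

A full synthetic study runs as

```r
pop  <- population_model("pk",
          links = list(covariate_link("Cld", "bsa", "exponential",
                                      coef = 1.17, ref = 1.30)))
coh  <- generate_cohort(cohort_spec(), seed = 1)
coh  <- simulate_observations(coh, pop, drift = drift_spec(), seed = 1)
p1   <- run_phase1(coh, "pk", seed = 1)          # fit + NCA + pcVPC + MC
p2   <- run_phase2(p1, coh)                      # adaptation procedures
```

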