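# pedpk

Population pharmacokinetics (popPK) for pediatric studies, and
between-drug extrapolation of CYP3A-mediated clearance from adults to
children.

## The problem

Dosing children rationally requires knowing how drug clearance changes
with body size, but dedicated PK studies cannot be run for every drug in
every pediatric age group. One validated shortcut is *between-drug
extrapolation*: estimate a covariate function for clearance from a probe
drug of the elimination pathway, then apply that function to scale the
adult clearance of other drugs sharing the pathway. For CYP3A — the
enzyme family clearing a large share of prescribed drugs — the probe is
midazolam. A hierarchical nonlinear mixed-effects (NLME) model fitted to
pediatric midazolam concentrations yields an allometric covariate
function,

```
CL_pediatric = CL_adult * (WT / 70)^0.874
```

with body weight `WT` in kg and a 70-kg reference adult. Whether this
function scales another CYP3A substrate accurately depends on the drug's
adult properties: its hepatic extraction ratio, its binding protein (HSA
or AAG), and its unbound fraction f_u. Accuracy is judged by the signed
prediction error against a pediatric reference clearance,

```
PE = (CL_scaled - CL_ref) / CL_ref * 100%
```

with |PE| < 30% accurate, 30-50% reasonably accurate, and >= 50%
inaccurate.

`pedpk` implements the whole pipeline in R:

* **Structural models** — analytical one- and two-compartment oral models
  (single dose and steady state), log-normal inter-individual variability
  `P_i = theta_TV * (COV_i/COV_med)^theta_COV * exp(eta_i)`, and the
  combined residual model `Y = C_pred * (1 + eps1) + eps2`.
* **Estimation** — a Laplace (FOCE-with-interaction family) marginal
  likelihood with a compiled inner optimizer, empirical Bayes estimates,
  conditional weighted residuals (CWRES), finite-difference standard
  errors, and stepwise covariate selection at the conventional
  ΔOFV 6.63 / 7.88 thresholds.
* **Evaluation** — nonparametric bootstrap (subject resampling) and
  normalized prediction distribution errors (NPDE).
* **Synthetic designs** — generators reproducing a dense single-dose
  midazolam-like study (31 children, 8-11 samples over 0.25-22 h) and a
  sparse steady-state sildenafil-like study (156 children, 1-4 samples,
  weight-stratified dosing), with the generating truth recorded.
* **Extrapolation** — clearance scaling, prediction errors, accuracy
  classes, and the drug-property criteria for when scaling is valid down
  to neonates.

## Worked example

Scaling an adult apparent clearance of 100 L/h (sildenafil-like) to
children, and comparing against a data-driven pediatric reference model
(113 L/h at 70 kg, exponent 1.08):

```r
library(pedpk)

sf <- ScalingFunction(clRef = 100)       # 70 kg reference, exponent 0.874
scaleClearance(sf, c(10, 20, 28, 50))
#> [1] 18.25510 33.45681 44.89525 74.52193

drugs <- data.frame(name = "sildenafil", cl_adult = 100,
                    ref_cl = 113, ref_wt = 70, ref_exp = 1.08)
peReport(drugs)
#>         name weight cl_scaled   cl_ref   pe            accuracy
#> 1 sildenafil     10  18.25510 13.81569 32.1 reasonably_accurate
#> 2 sildenafil     20  33.45681 29.20687 14.6            accurate
#> 3 sildenafil     50  74.52193 78.57062 -5.2            accurate
```

A 28-kg child receives 44.9 L/h from the extrapolation function; the
prediction error grows from -5.2% in a 50-kg adolescent to +32.1% in a
10-kg infant — the extrapolation increasingly overpredicts as weight
decreases, but stays at worst reasonably accurate.

Fitting the NLME model to a simulated dense midazolam-like study:

```r
study <- simulateMidazolamStudy(seed = 1)
study
#> PKStudy: 31 subjects, 296 observations, 31 dose records
#>   weight 27.0 kg (9.8-81.8), age 5.4 y (1.0-17.0)
#>   simulated (truth recorded)

fit <- fitModel(study, midazolamModel(), midazolamTruth())
fit
#> FitResult: OFV = -2368.618 (converged, 1250 evaluations)
#> ParameterSet
#>   thetas: cl=110, cl_wt=0.7575, vc=193, vc_wt=1.081, vp=271.3, vp_wt=0.9116, q=124.8
#>   omega2: cl=0.09631, vc=1.255
#>   sigma2: prop=0.3343 add=0
```

The typical apparent clearance at the 30.2-kg reference (110 L/h here)
and the weight exponent on clearance (0.76) recover the generating
values 102.6 L/h and 0.874 within the sampling noise of a 31-subject
study; medians over replicate seeds land much closer.

A thin command-line wrapper ships in `inst/cli/pedpk.R`
(`simulate | fit | bootstrap | npde | scale | evaluate-pe`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pedpk.R", package="pedpk"))')" \
    scale --cl-adult 100 --weight 28
#> 44.8952
```

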