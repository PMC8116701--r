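# iohexolPK

Population pharmacokinetics of iohexol in dogs, for estimating glomerular
filtration rate (GFR) from very few blood samples and for choosing *which*
samples to draw.

## The problem

Iohexol is a non-radioactive contrast agent that is freely filtered by the
glomerulus, essentially not secreted, reabsorbed or metabolised — so its
plasma clearance *is* the GFR. The classical measurement needs a full
concentration–time profile over several hours, which is impractical in the
clinic. A population pharmacokinetic (Pop PK) model changes the economics:
once the population distribution of the PK parameters is known, a single
dog's clearance can be estimated from one to three well-timed samples by
empirical Bayes, and the *best* sampling times can be chosen in advance
from the dog's covariates (kidney-disease status and serum creatinine).

This package is aimed at veterinary clinical pharmacologists and PK
modellers: it implements the full pipeline — structural model, Monte-Carlo
simulation, MAP estimation, sampling-design optimisation, non-compartmental
comparison, and population-parameter estimation — with a packaged
configuration holding published parameter estimates for a 49-dog cohort
(29 healthy, 20 with chronic kidney disease) given a 64.7 mg/kg IV bolus.

## The model

Disposition is two-compartmental with first-order elimination. For
individual *i*,

```
ln Cl_i = ln θ_Cl + θ1·1[CKD+] + θ2·(creat_i − 1.47) + η_Cl,i
V1_i    = θ_V1 · exp(η_V1,i)         V2_i = θ_V2 · exp(η_V2,i)
Q_i     = θ_Q                        η_i ~ N(0, Ω),  Ω diagonal
Y_ij    = f(t_ij; φ_i) · (1 + b·ε_ij),   ε_ij ~ N(0, 1)
```

with f the closed-form bi-exponential bolus solution and a proportional
residual error (b ≈ 6.2%). All parameters are per kg, so body weight
cancels. Given sparse observations `y` at times `K`, the empirical Bayes
(MAP) estimate minimises

```
J(η) = Σ_{t∈K} [ (y_t − f_t(η))² / g_t²(η) + ln g_t²(η) ] + η' Ω⁻¹ η,
g = b·f
```

by damped Gauss–Newton (compiled, multi-start). A candidate sampling
design `K` is scored by the Monte-Carlo mean squared error

```
MSE_K = (1/n) Σ_i ( η̂_Cl,i,K − η*_Cl,i )²
```

over n simulated dogs sharing the target dog's covariates — the average
squared log-scale distance between estimated and simulated clearance,
combining bias (eta-shrinkage) and imprecision. The design with the
smallest MSE_K is the recommended sampling schedule. A Laplace-approximate
nonlinear mixed-effects estimator (`fit_population()`) recovers the
population parameters from a long-format cohort dataset.

## Worked example

A CKD-positive dog with serum creatinine 1.7 mg/dl, sampled at 90 and
180 min after a 64.7 mg/kg bolus:

```r
library(iohexolPK)
pop <- load_population_config(system.file("extdata", "pop_published.yaml",
                                          package = "iohexolPK"))
dog <- dog_covariates(ckd = 1, creatinine = 1.7, id = "luna")
estimate_ebe(y = c(155.2, 101.8), times = c(90, 180), pop, dog,
             dose_per_kg = 64.7)
#> Empirical Bayes GFR estimate from 2 sample(s) at {90, 180} min
#>   Cl (GFR): 0.001285 L/min/kg = 1.285 ml/min/kg
#>   eta_hat: eta_cl = -0.02514, eta_v1 = 0.1286, eta_v2 = 0.03673
#>   objective 8.71137, converged in 8 iteration(s)
```

The dog's GFR estimate is 1.29 ml/min/kg — about the typical value for a
CKD+ dog at this creatinine (η_Cl near 0), i.e. well below the ~2.6
ml/min/kg of a healthy low-creatinine dog. Where should those samples have
been drawn? Rank all single-time candidates on the 30–180 min grid for
this covariate profile:

```r
best_times_for_dog(dog, pop,
                   simulation_config(times = seq(30, 180, 30),
                                     n_replicates = 2000, seed = 42),
                   max_samples = 1)
#> -- 1 sampling time(s) --
#>   times (min)    MSE (x10^-3) rank
#>   180            5.3173       1
#>   150            7.218        2
#>   120            12.209       3
#>   90             19.999       4
#>   60             29.403       5
#>   30             38.515       6
```

Late samples win for a slow-clearing CKD+ dog: 180 min is the best single
time, 150 min next — early samples mostly inform the distribution phase,
not clearance. For a healthy, low-creatinine dog the same computation puts
the optimum at 90–120 min. `run_full_reproduction()` executes this
analysis for three reference covariate profiles (healthy/creatinine 0.98,
CKD+/1.7, CKD+/2.25) over all 41 candidate 1-, 2- and 3-point designs and
writes the tables plus a cell-by-cell comparison against the packaged
reference values; see the methods vignette for what reproduces (the
ordering and every best-design recommendation) and what does not (the
absolute MSE magnitudes, which sit below the information bound of the
generating model — see `vignettes/iohexol-sampling-design.Rmd`).

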