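# thylakoidSAS

Small-angle scattering (SANS/SAXS) models for stacked double-bilayer
membrane systems — the thylakoid stacks of cyanobacteria measured *in
vivo*. The package is for structural biophysicists who have reduced 1D
scattering curves `(q, I, σ_I[, σ_q])` from such systems and want model-based
estimates of the repeat distance, membrane and lumen thicknesses, stack
size, and — from paired neutron/X-ray contrasts — the protein content of the
thylakoid lumen.

## The model

The powder-averaged intensity of a stack of `N` double-bilayer unit cells
with repeat distance `D` is

    I(q) = scale · 2π P(q) S(q) / (D q²) + B + C q⁻ⁿ

with the unit-cell form factor built from boxes (headgroups `d_H`, tails
`2·d_T`, lumen `d_L`; contrasts Δρ relative to the inter-thylakoid liquid)

    P(q) = (4/q²) [Δρ_H(sin qa − sin qb + sin qc − sin qd)
                   + Δρ_T(sin qb − sin qc) + Δρ_L sin qd]²,
    d = d_L/2,  c = d_L/2 + d_H,  b = d_L/2 + 2d_T + d_H,  a = b + d_H

and the finite-stack Caillé structure factor

    S(q) = 1 + 2 Σₙ₌₁^{N−1} (1 − n/N) cos(nqD) exp(−q²D²α(n)),
    α(n) = η_cp/(4π²) (ln(πn) + γ_E).

On top of this sit Gaussian polydispersity of the lumen width and repeat
distance (split-sum factorization), per-point Gaussian instrument-resolution
smearing, a Debye-equation point-cloud simulator that validates the analytic
expressions, a staged constrained χ² fitting engine with profile-likelihood
trust intervals, and an SLD scenario solver for the lumen composition. The
methods vignette (`vignettes/stacked-membrane-sas.Rmd`) documents every
modelling decision.

## Worked example

Simulate a curve from the Synechocystis-6803-like preset and fit it back:

```r
library(thylakoidSAS)

model <- presetModels()[["6803-like"]]   # D = 677.8 A, N = 4, dL = 62.13 A, ...
curve <- generateCurve(model, seed = 42) # 3% noise, 5% dq/q smearing
fit   <- stagedFit(fitProblem(curve))
fit
#> FitResult
#>   scale         1.00321
#>   D             677.764
#>   N             4.01624
#>   etaCP      0.00259642
#>   dL             62.147
#>   dT            16.8841
#>   rhoL         0.332362
#>   ...
#>   chi-square = 178.504, reduced = 0.939497 (n = 200, free = 10)
#>   deduced: dIT = 548.1, dTM = 33.77, physical = 1, peaksFound = 1, identifiable = 1
```

The fit recovers the ground truth (`D` to 0.005%, reduced χ² ≈ 0.94) and
reports the deduced inter-thylakoid gap `d_IT = D − d_L − 4·d_T ≈ 548 Å` and
membrane thickness `d_TM = 2·d_T ≈ 33.8 Å`. The contrast scenario solver
turns fitted relative lumen contrasts (neutron 0.34, X-ray −0.175) into a
composition estimate:

```r
top <- scenarioSearch()[1, ]
#> best scenario: IT 85% phycobilisome (w = 0, 100% D2O);
#> lumen protein 80.6% (neutron) / 80.6% (X-ray)
```

i.e. the lumen holds less protein than the inter-thylakoid space, with the
two radiations agreeing on ~81% under the default SLD table.

A command-line wrapper is installed as `exec/thylakoidSAS` with subcommands
`curve`, `synth`, `fit`, `debye` and `sld`, e.g.

    thylakoidSAS synth --preset 7002 --seed 7 --out data.dat
    thylakoidSAS fit --data data.dat --out report.txt

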