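---
title: "Modelling small-angle scattering from stacked double-bilayer membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling small-angle scattering from stacked double-bilayer membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thylakoidSAS)
```

# The problem

Cyanobacterial thylakoids are closed double-bilayer sheets enclosing an
aqueous lumen, stacked in the cell periphery with phycobilisome-rich
cytoplasmic liquid (the inter-thylakoid space, IT) between consecutive
sheets. Small-angle neutron and X-ray scattering (SANS/SAXS) probes this
ultrastructure *in vivo*, but a measured curve only becomes interpretable
through an explicit structural model: peak positions are modulated by the
form factor of the repeating unit, smeared by instrument resolution and by
the biological spread of the repeat and lumen distances, and sit on a
cell-wall power-law background. This package implements the full forward
model for such a system, a brute-force Debye-equation simulator used to
validate it, a staged constrained fitting engine, and a scattering-length
density (SLD) scenario solver that turns fitted contrasts into an estimate
of the lumenal protein content.

# The forward model

The powder-averaged intensity of a stack with repeat distance $D$ is

$$I(q) = \mathrm{scale}\cdot\frac{2\pi\,P(q)\,S(q)}{D\,q^{2}} + B + Cq^{-n},$$

the product of a unit-cell form factor and a finite-stack structure factor
with a flat-plus-power-law background.

## Double-bilayer form factor

The unit cell is one thylakoid: two bilayers (headgroup layers of width
$d_H$, tail regions of width $2d_T$) enclosing a lumen of width $d_L$, with
all contrasts $\Delta\rho$ measured relative to the IT liquid. Adding and
subtracting centered boxes on the amplitude level gives

$$P(q) = \frac{4}{q^{2}}\Big[\Delta\rho_H(\sin qa - \sin qb + \sin qc -
\sin qd) + \Delta\rho_T(\sin qb - \sin qc) + \Delta\rho_L\sin qd\Big]^{2}$$

with half-profile boundaries measured from the lumen midplane:

$$d = d_L/2,\quad c = d_L/2 + d_H,\quad b = d_L/2 + 2d_T + d_H,\quad
a = d_L/2 + 2d_T + 2d_H.$$

A published variant of this boundary algebra prints $c = d_L + d_H$. That
form makes the tail-region width depend on the lumen width and breaks the
$a-b = c-d = d_H$ symmetry that the amplitude grouping above requires, so
the symmetric convention is the default; `boundaries(geom, "printed")`
exposes the printed variant for comparison. `doubleBilayerFormFactor()` is
verified in the test suite against a numerical cosine transform of the
piecewise profile (an oracle that never touches the sine closed form) at
$10^{-6}$ relative tolerance, and its $q \to 0$ limit
$4(2d_H\Delta\rho_H + 2d_T\Delta\rho_T + \tfrac{d_L}{2}\Delta\rho_L)^2$ is
substituted analytically below $qa < 10^{-7}$.

With `dH = 0` the membrane collapses to a single box ("single-box membrane"
mode). Neutron contrast cannot resolve headgroups from tails in this system,
so all neutron fitting uses this mode with the tail contrast pinned at $-1$
and a free overall scale — the relative-contrast convention that the SLD
solver later inverts.

## Finite-stack structure factor

Assuming Gaussian fluctuations of each sheet around its lattice position,

$$S(q) = 1 + 2\sum_{n=1}^{N-1}\Big(1-\frac{n}{N}\Big)\cos(nqD)\,
e^{-q^{2}D^{2}\alpha(n)},\qquad
\alpha(n) = \frac{\eta_{cp}}{4\pi^{2}}\big(\ln(\pi n) + \gamma_E\big),$$

where $N$ is the number of thylakoids per stack and the Caillé parameter
$\eta_{cp}$ measures layer flexibility ($0$ = rigid flat sheets; the very
distinct higher-order peak cluster in cyanobacterial data requires
$\eta_{cp}$ to stay small). $\gamma_E$ is hard-coded as $0.5772156649$. At
$\eta_{cp}=0$ the sum telescopes to $S = N$ at $q \to 0$ and at every Bragg
position $2\pi n/D$, which the tests assert to $10^{-10}$.

Fitted stacks have non-integer average size (e.g. $N = 3.41$). $S(q)$ is
defined for integer $N$ only, so for fractional $N$ the two bracketing
integer stacks are evaluated and interpolated linearly by the fractional
part. Intensity is linear in $S$, so this equals interpolating the
intensities while keeping the fit surface continuous in $N$.

## Reading peak positions

The monotone $q^{-2}$ powder factor drags every intensity maximum slightly
below its Bragg position no matter how large $N$ is. Peak positions are
therefore read off the Lorentz-corrected curve $q^{2}I(q) \propto P(q)S(q)$,
the standard practice for lamellar powders. On that curve the model shows
the documented finite-size behaviour: for $N < 4$ the first-order maximum is
visibly displaced in the direction of the local form-factor slope, and from
$N = 4$ on it coincides with $2\pi/D$ within the resolution of a 2000-point
grid. This is why a single peak-position reading can misestimate the repeat
distance of a thin stack, and why different orders can shift in opposite
directions while belonging to one lattice.

## Background

$I_b = B + Cq^{-n}$ absorbs the incoherent flat level and cell-wall
scattering; $n$ is constrained to $[1.5, 2.6]$ during fitting, around the
theoretically expected $q^{-2}$.

# Polydispersity and instrument resolution

Biological stacks have distributed repeat and lumen distances. Both are
modelled as Gaussians sampled on a fixed symmetric grid (`gaussianGrid()`,
default 21 nodes truncated at $3\sigma$, weights renormalized after dropping
nodes that would make a thickness non-positive). Instead of the full double
sum over the $(d_L, D)$ product grid, `polydisperseIntensity()` factorizes:
the lumen-averaged form factor is computed first and then reused inside the
repeat-distance sum. The tests show the split agrees with the full double
sum to better than 0.5% everywhere while being an order of magnitude
cheaper.

The two mechanisms act differently: lumen polydispersity fills in the deep
form-factor minimum at $q \approx 0.01$–$0.03\,\mathrm{\AA^{-1}}$
(monotonically in $\sigma_L$, asserted over $\sigma_L \in \{0,5,10,15,20\}$ Å),
while repeat-distance polydispersity damps high-$q$ structure much like an
increased Caillé parameter (asserted as a rank correlation between the two
damping ratios). The default fitting model therefore keeps lumen
polydispersity available explicitly (`sigmaL`, fixed at 0 unless freed) and
folds repeat-distance fluctuations into $\eta_{cp}$; the $\sigma_D$
machinery remains for studies.

Instrument resolution is a per-point Gaussian in $q$:
$I_s(q_i) = \sum_j w_j I(q_i + x_j\sigma_{q,i})$ on the same kind of fixed
node grid, with nodes below $q = 10^{-4}\,\mathrm{\AA^{-1}}$ dropped and the
weights renormalized (the model is undefined at $q \le 0$). $\sigma_q$ comes
from the fourth column of a reduced data file or a configured constant;
$\sigma_q = 0$ rows pass through exactly. Smearing is essential for neutron
data; SAXS curves are conventionally fitted unsmeared. The quadrature
choices (21 nodes, $3\sigma$ cutoff) follow the accuracy checks in the test
suite: a Gaussian peak of width $w$ smeared by $\sigma_q$ comes out with
width $\sqrt{w^2+\sigma_q^2}$ within 2%, and compact peaks conserve their
integral.

# The Debye-equation validation simulator

The analytic model is validated against a geometry-free brute-force route:
fill each slab region of a disc-shaped unit cell (radius 1000 Å, so the disc
envelope sits below the probed $q$ range) with uniformly random points, give
every point of region $k$ the scattering length
$b_i = \Delta\rho_k V_k / n_k$ (region totals then equal contrast × volume
for any point split), stack $N$ translated copies at spacing $D$, and sum

$$I(q) = \sum_i\sum_j b_i b_j \frac{\sin(qr_{ij})}{qr_{ij}}.$$

In-plane positions are drawn uniformly in area ($r = R\sqrt{u}$); points are
allocated to regions by largest remainder so counts are proportional to
region volumes. All stochastic operations require a seed, which is recorded
in the object and in every output file.

Two compiled engines back `debyeIntensity()`: an exact pair sum (the
contract checked against a naive R double loop at $10^{-10}$ relative
tolerance) and a distance-binned engine for large clouds, which accumulates
the zeroth and first moments of $b_ib_j$ per distance bin and expands the
sinc kernel to first order about each bin centre — with the default 0.25 Å
bins the truncation error is orders of magnitude below Monte-Carlo noise.
The exact engine refuses pair counts above a configurable ceiling rather
than silently consuming memory and hours.

A finite point cloud is a discretized continuum: its Debye sum carries a
known offset, the self term $\sum_i b_i^2$, and its continuum limit equals
$N_{\mathrm{cells}} \pi R^2 D \cdot I_{\mathrm{model}}(q)$ for the
monodisperse rigid model. The validation therefore compares the simulated
curve against this fully deterministic prediction — no fitted scale — and
finds median relative deviations of 1–2% for $N = 1..3$ cells at $10^4$
points per cell, excluding small neighbourhoods of the form-factor minima
where a finite sample is dominated by Monte-Carlo noise (the test excludes
±4 bins of the 200-bin grid around each minimum of $P(q)$). The desk-scale
default of $10^4$ points per cell keeps one validation run in seconds;
the point count is configurable and deviations shrink as points are added
(a convergence property the tests assert by doubling the count).

# Staged fitting

`stagedFit()` minimizes $\chi^2 = \sum\big((I_{\mathrm{data}} -
I_{\mathrm{model}})/\sigma_I\big)^2$ under box constraints reflecting the
biology: total membrane thickness $2d_T \in [20, 60]$ Å, lumen
$d_L \in [45, 300]$ Å, repeat distance $D \in [450, 950]$ Å, stack size
$N \in [2, 6]$, $\eta_{cp} \in [0, 0.2]$, $n \in [1.5, 2.6]$.

1. **Repeat distance.** The higher-order peak cluster around
   $q \approx 0.05\,\mathrm{\AA^{-1}}$ pins $D$. Local maxima of the
   smoothed log-intensity establish that a cluster exists; $D$ itself is
   estimated by scanning candidates over $[450, 950]$ Å and scoring the
   smoothed intensity at the Bragg comb $2\pi n/D$ ($n = 2..6$) *minus* the
   half-order midpoints. The contrast term rejects harmonics, and the comb
   uses all orders jointly — on a 200-point smeared grid the spacing of
   individual detected maxima is quantized to the bin width, which makes a
   median-of-spacings estimate unreliable (errors of 20% were observed),
   while the comb scan recovers $D$ to better than 1%. If no maxima are
   found at all, the stage is skipped with a warning and a direct global fit
   attempted (`deduced$peaksFound = FALSE`).
2. **Single-box membrane.** With the stack frozen, the widths, lumen
   contrast, scale and background are released; these control the relative
   heights of the characteristic three-peak pattern.
3. **Global refinement.** A coarse grid over $N \in \{2..6\}$ and
   log-spaced $\eta_{cp} \in [10^{-4}, 0.1]$ is scored at the stage-2
   parameters; the best cell of *every* candidate $N$ is refined by bounded
   Levenberg–Marquardt (`minpack.lm::nls.lm`) with all free parameters
   released (the $N$/$\eta_{cp}$ damping degeneracy makes refining a single
   cell unreliable), and a final refinement treats $N$ as continuous via the
   interpolated structure factor, started from the best few integer-$N$
   results because the surface is only piecewise smooth in $N$. Equal
   chi-squares break toward the smaller Caillé parameter — the stiffer,
   simpler model.

The trace of accepted stages is monotone non-increasing in $\chi^2$ and the
whole procedure is deterministic, so identical inputs give bit-identical
fits. Two flags qualify the result: `peaksFound` (stage 1) and
`identifiable`, which is `FALSE` when the structure term is statistically
unnecessary — removing it (scale to its lower bound) must cost more than
ten $\chi^2$ units per free structural parameter, since a flexible
structure term absorbs about one unit of noise per parameter even on
structureless data — or when $\chi^2$ is flat along $D$. Pure-background
input is the canonical unidentifiable case and is exercised in the tests.

`profileLikelihood()` provides trust intervals: the parameter walks outward
from its optimum in geometrically growing steps, re-optimizing all other
free parameters at each probe, until $\chi^2$ rises by `deltaChisq`
(default 1.0, the one-parameter 68% region) or a bound is hit; the crossing
is located by interpolation, flat directions are widened to the bound with
a warning, and fixed parameters return degenerate intervals. On an exactly
quadratic surface (the overall scale with everything else fixed) the
interval matches the curvature-based standard deviation within 5%.

# SLD composition and the lumen-content solver

Absolute SLDs cannot be composed for the IT liquid without knowing its
protein content, so fitting uses relative contrasts: IT maps to 0 and the
membrane anchor to $-1$, i.e.
$\mathrm{rel}(x) = (SLD_{IT} - x)/(SLD_{TM} - SLD_{IT})$, with the exact
inverse $x = SLD_{IT} + \mathrm{rel}\cdot(SLD_{IT} - SLD_{TM})$
(round-trips to machine precision in the tests). The neutron anchor is the
single-box membrane SLD $SLD_{TM} = \tfrac12(SLD_{T,\mathrm{avg}} +
SLD_{H,\mathrm{avg}})$ of protein-averaged tail and head regions
(protein/lipid 0.7/0.3); with the worked inputs
$1.832$ and $1.327\times10^{-6}\,\mathrm{\AA^{-2}}$ this gives
$1.58\times10^{-6}\,\mathrm{\AA^{-2}}$. The X-ray anchor is the tail SLD.

`scenarioSearch()` solves the coupled system linking the two radiations.
For each IT scenario — phycobilisome volume fraction
$\phi \in [0.60, 0.85]$, labile H–D exchange $w \in [0, 0.9]$, D2O fraction
of the IT water — the absolute IT SLDs are composed as volume-weighted sums
(water terms enter as $\phi_{D_2O} SLD_{D_2O} + \phi_{H_2O} SLD_{H_2O}$;
a ratio notation sometimes seen for this term is not dimensionally
consistent and is not used). The fitted relative lumen contrasts
($C_1 = 0.34$ neutron, $C_2 = -0.175$ X-ray in the reference analysis) then
map to absolute lumen SLDs through the inverse relative-contrast transform
above — the only reading that reproduces the published absolute lumen SLDs
($4.29$–$4.41\times10^{-6}\,\mathrm{\AA^{-2}}$ arise exactly from
$SLD_{IT,N} = 3.61\times10^{-6}$ and the three fitted contrasts). Each
branch is a two-component mixture solved for the lumen protein fraction,
with the lumen water D2O level constrained not to exceed the IT level
(lumenal water exchanges with the cytoplasm). Scenarios are ranked by
$|\phi_N - \phi_X|$: where two independent radiations imply the same lumen
protein content is the most credible composition.

Two caveats are deliberate. First, the component SLD table
(`defaultSLDTable()`, units $10^{-6}\,\mathrm{\AA^{-2}}$) holds standard
literature values — heavy/light water, galactolipid heads, unsaturated
tails, globular and phycobiliprotein SLDs with linear interpolation in the
labile-exchange fraction — checked against the published IT ranges but not
transcribed from any supplementary source; it is an editable input, and
sequence-derived values should replace it when available. Second, the score
landscape is nearly degenerate: many IT scenarios admit a lumen composition
that reconciles the two radiations to $|\phi_N - \phi_X| < 10^{-3}$, so
refining the grids can reshuffle the near-optimal set. The solver therefore
returns the full ranked table, and the robust scientific statement — the
one the tests assert — is the ordering: the best-ranked scenario puts
strictly less protein in the lumen than in the IT space. With the default
table and the reference contrasts the top scenario is 85% phycobilisome IT
with ~81% lumen protein.

# Synthetic data

`generateCurve()` produces the curves every other module is tested on: the
smeared model on 200 bins over $0.005$–$0.3\,\mathrm{\AA^{-1}}$, 3% relative
Gaussian noise with the noise sigma reported as the $\sigma_I$ column, a
constant $\sigma_q/q = 5\%$ resolution profile, a mandatory seed, and the
complete ground truth embedded in the metadata. These are plausible
reduced-SANS conditions; they are configurable but the defaults define the
package's study conditions. Residuals over many seeds pass a mean-zero,
unit-variance sanity check in the tests.

Three presets (`presetModels()`) use the published average SANS fit values
(repeat distance, stack size, lumen and tail thicknesses, relative lumen
contrast) of the strains 6803, 7942 and 7002 as ground truth. The presets
set $\eta_{cp} = 0.003$ (stiff stacks, consistent with the resolved peak
cluster), zero background and zero lumen polydispersity: the recovery study
isolates the stack parameters, and the polydispersity and background terms
are exercised by their own tests. The acceptance study fits 20 synthetic
curves at the default noise and smearing across the three presets and
recovers $D$ within 2% and $d_L$, $d_T$ within 10% (observed errors are
well under 0.5%), with the signed bias of $D$ below one recovery standard
deviation per preset. Real-data fits would face contrast imperfections,
multiple scattering and structural heterogeneity that these synthetic
conditions do not emulate, so recovery success validates the inference
machinery, not the biology.

`lognormalNumberMean()` reconciles volume-weighted (scattering) and
number-weighted (microscopy) repeat-distance means: for a log-normal with
shape $\sigma$, weighting by the $p$-th power of the size shifts the
log-mean by $p\sigma^2$, so the number mean is the volume mean times
$e^{-p\sigma^2}$ ($p = 3$ by default; the shape parameter is an input
because published values of it vary by convention). A Monte-Carlo
reweighting of $10^6$ draws agrees within 0.5% in the tests. With
$\sigma = 0.23$, a 690 Å volume-weighted mean corresponds to a ~589 Å
number mean, reconciling scattering-derived and microscopy-derived repeat
distances.

# Numerical choices and problem sizes

* $q = 0$ is never evaluated in intensity expressions; curves start at the
  instrument minimum and the analytic small-$q$ limits exist for testing.
* All file writers are deterministic (sorted header keys, fixed `%.17g`
  formatting), so seeded CLI runs are byte-identical.
* Test problem sizes: 100 random geometries for the form-factor oracle,
  $10^4$ points/cell and $N \le 3$ for Debye validation, 20 fits for the
  recovery study, 50 seeds for distributional checks — sizes chosen so the
  whole suite runs in a few minutes on one core while keeping every check
  statistically meaningful.

# Limitations

* No slit smearing (SAXS line collimation) and no absolute-intensity
  calibration; the model works in relative contrast with one overall scale.
* The structure factor is the printed finite-$N$ Caillé form; no additional
  fluctuation-dependent normalization is applied.
* The scenario solver's discrete ranking cannot distinguish near-tied
  compositions; treat its output as a ranked shortlist under explicit
  assumptions, not a posterior.
* 2D detector images, time-of-flight reduction and multi-contrast global
  fits are out of scope; curves are fitted one contrast at a time.
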