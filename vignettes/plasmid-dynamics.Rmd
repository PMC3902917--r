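---
title: "Models and methods for high-copy plasmid dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for high-copy plasmid dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidyn)
```

`plasmidyn` packages the quantitative toolbox for studying how high-copy
ColE1-type plasmids move, replicate and segregate in rod-shaped bacteria.
This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical decisions taken where the design was
genuinely open, and what the test suite does and does not demonstrate.

## Coordinate and unit conventions

Positions along the cell's long axis are either absolute (µm, pole at 0) or
relative in [0, 1] with the septum at 0.5; distance to the nearest pole is
`min(p, 1 - p)`. The short axis is measured from the centreline. Units are
embedded in column names (`x_um`, `t_s`, `time_min`) and every stochastic
function takes one explicit integer seed, so all outputs are bit-reproducible.

## Confined diffusion and MSD analysis

A plasmid spot tracked at interval `dt` yields a time-averaged mean square
displacement per axis; `compute_msd()` averages squared displacements over
*all* ordered frame pairs at each lag (an `ensemble` mode restricted to
displacements from the first frame is provided for synchronised-ensemble
work). The estimator is deliberately the plain O(n·k) pair average on the
native lag grid — no interpolation between lags — and the test suite pins it
to an independent O(n²) brute-force oracle.

Confinement is quantified with the single-exponential approximation of the
confined-diffusion (Kusumi-type) series,

$$\mathrm{MSD}(t) = \frac{L^2}{6}\left(1 - e^{-12 D t / L^2}\right) + c,$$

whose asymptote $L^2/6$ measures the confinement length $L$ on that axis and
whose initial slope is $2Dt$. `fit_confinement()` minimises weighted squared
error (weights = number of displacement pairs per lag) by
Levenberg–Marquardt from a 3×3 multi-start grid seeded by the curve's tail
plateau and initial secant; a fit that fails from every start is returned
flagged rather than erroring. The constant $c$ is an optional
localization-noise floor and is **off by default**: spot-tracking studies of
this kind generally fit without one, and the synthetic generator lets you
study its effect explicitly when you switch it on.

Two numerical choices deserve note:

* **Plateau classification.** A fit is `plateau_reached` when the fitted $L$
  does not exceed the cell dimension on that axis *and* the observation span
  covers at least three relaxation times $L^2/(12D)$. The threshold of three
  relaxation times is our choice; the qualitative criterion (curves still
  rising at the longest lag are excluded from confinement averages) is
  standard practice for tracks whose apparent confinement exceeds the cell.
* **Dimensionality factor.** `compute_dapp()` implements
  $D_\mathrm{app} = \mathrm{MSD}/(\tau q_i)$ with $q_i = 2$ for a single
  axis and $4$ in 2D. Applying this formula to the classic literature value
  of a 0.20 µm mean positional change per 5 s gives
  $2.0\times10^{-3}\,\mu m^2/s$, not the $0.4\times10^{-3}$ sometimes quoted
  for that plasmid; the package reproduces the formula and leaves the
  discrepancy documented rather than resolved.

## Hop diffusion and nucleoid exclusion

The generator `gen_confined_trajectory()` produces Brownian motion with
Gaussian increments of variance $2D\,dt$ per axis, confined by specular
reflection. Reflection is implemented by *folding* the free cumulative path
into the box, which is exact for a reflecting interval and preserves the
uniform stationary distribution (long-run positional variance $L^2/12$, a
tested invariant). Localization noise is added to observed positions only —
camera error does not feed back into the dynamics.

`gen_hop_trajectory()` adds partially permeable nucleoid intervals on the
long axis. A step whose segment would **enter** a nucleoid interval is
accepted whole with probability `p_hop` and otherwise reflected specularly
at the entry boundary; steps **leaving** an interval are free. The one-sided
gate was a genuine design decision: gating both directions symmetrically
satisfies detailed balance and therefore leaves the stationary distribution
uniform — a particle would spend time in the nucleoid in proportion to its
length, which is exactly what nucleoid exclusion does *not* look like. The
entry-only gate realises exclusion as an entropic barrier: at stationarity
the density inside the nucleoid is depressed by a factor of order `p_hop`,
`p_hop = 1` degenerates to plain confined diffusion (uniform occupancy, a
KS-tested invariant), and `p_hop = 0` makes the nucleoid impenetrable from
outside. Polar occupancy then rises monotonically as `p_hop` falls, giving
the characteristic polar-fraction enrichment of nucleoid-excluded cargo.

There is no measured localization error for the tracked spots, so
`loc_noise_sd` is a configuration value with no default claim attached.

## qPCR quantification and the cell-cycle copy-number model

`qpcr_ratio()` is efficiency-corrected ΔΔCt against the chromosomal *oriC*
target with calibrator wells:
$\mathrm{ratio} = E_{pl}^{\,Ct^{cal}_{pl} - Ct_{pl}} / E_{chr}^{\,Ct^{cal}_{chr} - Ct_{chr}}$,
using mean Ct per target; the result is invariant to instrument-wide Ct
shifts. Efficiencies default to 2 (perfect doubling) unless supplied.
Mean origins per cell come from the exponential-culture formula
$2^{(C+D)/\tau}$; the default $C + D = 92.6$ min at $\tau = 100$ min
reproduces the 1.9 origins per cell appropriate to slow growth in glycerol
minimal medium. Whether that literature value was itself derived from this
formula or from a fuller cell-cycle simulation is not documented; treating
$C + D$ as a configuration input keeps the choice explicit.

The cell-cycle model closes the copy-number bookkeeping. With exponential
growth, the steady-state age density is $f(x) = 2\ln 2\cdot 2^{-x}$ on
$[0,1]$. Writing $p(x) = m\,2^x$ and requiring
$\int_0^1 p(x) f(x)\,dx = k$ (the culture-average copy number actually
measured) forces $m = k/(2\ln 2)$ — the unique closure, verified in the
tests against a Monte-Carlo average over $10^6$ sampled ages. With
$k = 17$: 12.3 copies at birth, 24.5 at division.

## Stochastic replication statistics

If each of the $n$ plasmids present at birth is duplicated once per
generation on average, initiations occur every $\tau/n$ minutes (8.3 min
for 12 copies at $\tau = 100$). `interval_by_length()` computes the
empirical analogue — consecutive event-start differences per cell, binned
by cell length; event *lifetimes* never affect intervals. Marker lifetimes
decompose as synthesis time plus retention:
$\mathrm{bp}/v_{fork} + t_{ret}$, so an 11.3-kb plasmid at ~600 bp/s gives
~19 s for an SSB-like marker and a ~283-s clamp retention reproduces a
~302-s DnaN-like lifetime.

EdU spot counts per cell after a window of $t$ minutes are modelled as
Poisson with mean $\lambda = t/t_1$; `edu_calibrate()` estimates the rate
$1/t_1$ by least squares through the origin on mean-count-versus-time. The
rate is **per cell**, not per plasmid: the observable is a per-cell count
(the per-plasmid interpretation lives in the simulator). The closed-form
multiplicity ratios are $P(1)/P(2) = 2/\lambda$ and $P(1)/P(3) = 6/\lambda^2$
(identically $r_{13} = 1.5\,r_{12}^2$). At the 17.6-min calibration and a
6-min window, $r_{13} = 51.6$ — agreeing with the observed ~50-fold excess —
while $r_{12} = 5.9$ exceeds the observed ~4-fold value; the package
reports both and does not adjust either, since no single Poisson rate can
match both printed ratios at once. Goodness of fit uses a chi-square on
bins $\{0, 1, 2, \ge 3\}$ with the rate fixed by calibration (not
re-estimated), the tail collapsed so expected counts stay usable at a few
hundred cells; its size and power are checked by simulation.

## The whole-cell simulator

`sim_run()` follows one cell lineage. Within a generation the cell
elongates exponentially (doubling over $\tau$; division is a deterministic
timer — no size-control law is assumed), plasmid positions rescale with
growth, and each plasmid takes a hop-diffusion step against the current
nucleoid: a single central block covering `nucleoid_fraction` of the length
that splits into two blocks around a midcell gap at cell-cycle stage
`nucleoid_split_x` (default 0.75), mirroring the late-cycle midcell
accumulation of plasmids before nucleoid separation. Completed replications
place the new copy at the parent's position with a 0.01-µm jitter — no
cohesion period. At division the septum sits at relative position 0.5 and
each plasmid goes to the daughter whose half it occupies (ties by fair
coin); counts are always conserved, and the daughter's nucleoid resets to a
single central block.

Replication has two modes:

* `constant_rate` — every non-replicating plasmid initiates with fixed
  probability per unit time, calibrated to $\ln 2/\tau$ so copies double
  per generation *in expectation*. This is the pure constant-probability
  model. It is a critical branching process: the cross-lineage mean is
  conserved (a tested invariant) but individual lineages fluctuate without
  bound, so it cannot by itself explain inheritance that stays stable for
  ~70 generations.
* `rnaI_feedback` — the base rate is divided by $1 + n/K$, a well-mixed
  antisense RNA I pool inhibiting primer maturation in proportion to total
  copy number $n$. RNA I is present at a few hundred molecules per cell and
  equilibrates across the cell quickly, which is also why initiation
  probability is position-independent in the model. We place the
  half-inhibition constant at $K = 2$ copies, deep in the saturated regime
  where the *total* initiation rate is nearly independent of copy number —
  the hallmark of ColE1-type control — and calibrate the base rate so the
  deterministic trajectory still doubles over one generation from
  `n_birth` copies: $r_0 = (\ln 2 + n_{birth}/K)/\tau$. With this choice
  single-lineage birth copy number is homeostatic (stationary mean within a
  few percent of `n_birth`) and plasmid-free daughters are produced at
  below $10^{-4}$ per division.

One discretisation detail: in the multi-lineage projection
(`sim_lineages()`, below) the per-sub-step initiation probability is
`expm1(rate · dt)` rather than `rate · dt`, so that expected growth
compounds to exactly $e^{\mathrm{rate}\,\tau}$ per generation; with the
naive product the constant-rate mode drifts measurably subcritical over
hundreds of generations.

**Loss statistics.** With $n$ copies at division partitioned
binomially, a daughter is plasmid-free with probability $2(1/2)^n$ —
$1.2\times10^{-7}$ at 24 copies, which would predict essentially zero
losses over 70 000 divisions. In the full stochastic model copy number
fluctuates (Poisson initiation plus binomial partition give a stationary
SD of ~3.5 copies around a mean of 12 at birth), and the loss probability
is dominated by rare low-copy excursions; realised loss rates are
therefore above the fixed-copy bound, though still below $10^{-4}$ per
division at calibrated feedback. The tests assert both statements
separately rather than pretending the fixed-copy bound applies to the
fluctuating process.

**Problem sizes.** Spatial test runs use a time-scaled system: generation
time shortened tenfold with the diffusion coefficient raised tenfold,
preserving the dimensionless mixing ratio $D\tau/L^2$ that controls how
often a plasmid changes compartment per cell cycle, and a 0.25-s step so
diffusion steps stay small against the nucleoid-free zones. (Shortening
$\tau$ alone freezes plasmids in their birth compartment, replication then
amplifies one pole, and lineages collapse — a scaling artifact, not a
property of the model.) Multi-generation loss and homeostasis statistics
use `sim_lineages()`, the copy-number projection of the same model
(identical initiation law; `Binomial(n, 1/2)` partition, which is what the
positional rule produces at a symmetric steady state — itself verified
spatially through `sim_divide()` on stationary hop-diffusion samples).
Typical suite sizes: 200 tracks × 120 frames for confinement recovery,
$10^4$ divisions for the partition chi-square, 1000 lineages × 70
generations for loss statistics.

**Gyration size.** `gyration_diameter()` interpolates a power law
$d = A\,\mathrm{bp}^\nu$ through calibration points for supercoiled
plasmids. The bundled table is *synthetic* — ideal-coil scaling
($\nu = 0.5$) anchored so 11.3 kb maps to 265 nm — because the underlying
literature calibration points are not available in numeric form; it is a
configuration default, not derived truth. Whether "diameter of gyration"
means exactly twice the radius of gyration is likewise not pinned down by
the sources that quote it; the anchor value is used as-is.

## Synthetic data: what the generators do and do not emulate

The generators produce every input class the estimators consume, each with
known ground truth: reflecting-box and hop-diffusion tracks with optional
localization noise at 0.5–10 s sampling; qPCR plates whose Ct structure
encodes an exact target ratio under chosen amplification efficiencies;
Poisson EdU counts; Gaussian-spot images with read noise for the minimal
localizer (`localize_spots()`, a local-maximum + centroid refiner whose
candidate detection runs on a 3×3-mean-smoothed image so a 3-SD threshold
is not tripped by single-pixel noise).

They deliberately do **not** emulate: photophysics (bleaching, blinking),
3D point-spread functions, plasmid–plasmid crowding or clustering,
multimers and catenanes, EdU incorporation efficiency, or segmentation
error in cell outlines. Passing recovery tests therefore demonstrates that
the estimators are correct *for the generative models stated above* — that
the MSD fit recovers a true reflecting-box confinement, that ΔΔCt recovers
a true ratio — not that real micrographs are free of the systematic effects
the generators omit.

## Known limitations

* The confined-diffusion fit assumes a single static compartment per axis;
  no drift correction, no state-switching (HMM) analysis, no 3D.
* The simulator's nucleoid is a static envelope (one block, then two); it
  does not model chromosome replication or segregation dynamics, RNA
  I/RNA II hybridisation kinetics, or multimer resolution.
* `constant_rate` mode is intentionally non-homeostatic (see above); use
  `rnaI_feedback` for any multi-generation question.
* Quantification is relative (plasmid:oriC); absolute quantification from
  mass standard curves is out of scope.
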