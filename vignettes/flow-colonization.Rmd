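---
title: "Modelling bacterial surface colonization under flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bacterial surface colonization under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowcolonize)
```

## The model

Early biofilm growth on the floor of a microchannel is shaped by a
competition between two transport processes acting on planktonic daughter
cells. Flow advects a cell toward the outlet in a residence time
$\tau_a = L/v$, where $L$ is the channel length and $v$ the mean flow
velocity. Unbiased swimming lets a cell explore the channel depth $h$ like
a Brownian particle with effective diffusivity $D$, reaching the floor on a
timescale $\tau_D = h^2/D$. Their ratio

$$\mathrm{Pe} = \frac{\tau_D}{\tau_a} = \frac{h^2 v}{D L}$$

is a Péclet number: at small Pe a released cell has ample time to find the
floor and reattach near-ish its origin; at large Pe it is washed out first.
`peclet()` and `transport_scales()` compute these quantities; all internal
units are SI, with converters (`um_to_m()`, `ul_min_to_m3_s()`, ...) at the
boundary because microfluidics practice mixes four unit systems and silent
unit errors are the main failure mode of such calculations. The
still-fluid limit is defined, not an error: $v = 0$ gives $\tau_a = \infty$
and $\mathrm{Pe} = 0$, so limiting behaviour remains testable.

A timescale argument alone does not fix the *probability* of attachment; a
microscopic attachment rule is needed. A perfectly absorbing floor would
give a capture probability falling like $\mathrm{Pe}^{-1/2}$ to
$\mathrm{Pe}^{-1/3}$ (a boundary-layer result), steeper than the
$\mathrm{Pe}^{-1}$ law this class of attachment measurements exhibits. We
therefore model the floor as *partially* absorbing with reactivity
$\kappa$ (m s$^{-1}$) and operate in the reaction-limited regime
$\kappa h / D < 0.1$, where a cell crosses the depth many times before
sticking, is effectively well mixed, and attaches at rate $\kappa/h$ during
its residence $L/v$:

$$p_\mathrm{att} = 1 - \exp\!\left(-\frac{\kappa L}{v h}\right),
\qquad \frac{\kappa L}{v h} = \frac{\kappa h}{D}\,\mathrm{Pe}^{-1},$$

hence $p_\mathrm{att} \propto \mathrm{Pe}^{-1}$ whenever $p$ is small
(`analytic_attachment_probability()`, which refuses to evaluate outside the
reaction-limited regime where the formula is wrong). The default
dimensionless reactivity is $\kappa h / D = 0.01$; it is the one genuinely
free parameter of the transport model, absorbing everything unknown about
adhesin kinetics, and also any offset from the fact that real inlet
suspensions mix adhesion-competent and incompetent cells.

## Brownian-dynamics transport simulator

`simulate_transport()` integrates $x \leftarrow x + u(z)\,dt$ (plug profile
by default; the plane-Poiseuille profile $u = 6v\,(z/h)(1-z/h)$ is
available for sensitivity analysis) and
$z \leftarrow z + \sqrt{2 D\, dt}\,\xi$ with reflecting ceiling. A floor
crossing sticks with the per-contact probability
$P = \kappa\sqrt{\pi\,dt/D}$ (`sticking_probability()`); this $\sqrt{dt}$
scaling is what makes the continuum absorption rate independent of the
timestep, and the suite checks that halving $dt$ moves the estimate by
less than three pooled standard errors. The default timestep obeys two
resolution rules, $\sqrt{2D\,dt} \le h/50$ and $v\,dt \le L/100$; runs are
capped at ten residence times. Transport is simulated in the $x$–$z$ plane
only: the channels are several times wider than tall, and only the floor
is quantified, so sidewalls and the lateral coordinate are irrelevant to
capture statistics.

A statistical caveat worth stating explicitly: with $\kappa h/D = 0.01$
the expected number of attachment events in a batch of $2\times 10^4$
particles is only $0.01/\mathrm{Pe} \times 2\times10^4$ — about 2 at
$\mathrm{Pe} = 100$ and below 1 at $\mathrm{Pe} = 300$. A log–log slope
fitted to batches of that size has a standard deviation of about 0.14 and
must drop zero-count conditions, which biases it; batch sizes giving at
least ~40 expected events per condition (as used in
`analysis/01_transport_scaling.R` and `scripts/acceptance.R`) bring the
slope standard deviation down to ~0.04. Exponent estimates from
small-event-count batches should be treated accordingly.

## Agent-based colonization simulator

`run_colonization()` grows a population of surface-anchored mother cells
that divide asymmetrically. Division intervals are gamma-distributed with
mean `T_div = 5400` s and CV 0.15 — a 90-minute doubling, typical for this
organism in rich medium at 30 °C; the CV is a generic cell-cycle
variability. At each division the daughter either

* attaches immediately downstream of its mother (probability
  `p_near = 0.4`), at a 2 µm offset (one cell length) with 0.3 µm
  isotropic jitter — the cell-shape-assisted local capture mode, which is
  motility-independent; or
* is released into the bulk, where `bulk_fate()` draws an exponential
  waiting time to reattachment and the flow decides between reattachment at
  $x' = x + v t$ (with lateral diffusion, reflected at the sidewalls) and
  washout past the outlet.

`p_near` has no printed experimental value; 0.4 is a calibration knob
declared as such, with a plausible range of roughly 0.2–0.6, identical for
motile and nonmotile cells. Attachment is irreversible (holdfast), there
is no detachment, no mechanical interaction, and overlapping cells are
permitted — density is handled at rendering.

The bulk waiting-time rate is $1/(h/\kappa + h^2/2D)$: the reactive
resistance and the cross-depth diffusion resistance in series. In the
motile, reaction-limited regime this is $\kappa/h$ within half a percent,
so the simulator's implied attachment probability matches the transport
module's closed form (the suite verifies this against
$1-e^{-\kappa L /(vh)}$ to three binomial standard errors). The series
form matters for the nonmotile mode (`D = D_PASSIVE`, reactivity
unchanged): a passive daughter reaches the floor so slowly that its
attachment rate drops by an order of magnitude, which is what makes
flagellum-less populations colonize more slowly and in more segregated
clusters at low flow. A pure $\kappa/h$ rate would make the attachment
rate independent of $D$ and erase the motility phenotype entirely, which
is why the series form replaces it.

A consequence of the weak default reactivity deserves emphasis because it
bounds what the generator can reproduce. At $\kappa h/D = 0.01$ and
$v = 2$ mm s$^{-1}$, a bulk daughter's reattachment probability is about
0.25%, so reattachment-seeded young colonies are rare, and the colony-size
statistics at 24 h are dominated by local growth — which is
flow-independent by construction. Median microcolony area therefore comes
out near 30–35 µm² at *both* weak and strong flow
(`analysis/02_colonization_patterns.R`), rather than splitting into the
<40 µm² / >100 µm² regimes seen experimentally. Recalibrating `p_near`
within 0.3–0.5 or `T_div` within 4500–7200 s moves both velocities
together (22–40 µm² across the grid) and cannot create the split. Two
model ingredients would be needed: a larger reactivity
($\kappa h/D \approx 0.09$, still reaction-limited, makes weak-flow fields
fill with young reattachment-seeded colonies and restores the direction of
the size contrast — see the sensitivity block of `analysis/02`), and a
two-dimensional local-placement rule: the fixed downstream offset makes
clonal colonies quasi-one-dimensional comets whose rendered footprint
saturates near 35 µm² no matter how many cells they contain, whereas real
colonies spread laterally by steric repulsion, which this simulator
deliberately omits. Both are documented here rather than silently tuned,
since the defaults are part of the declared study conditions.

## Synthetic images and ground truth

`render_population()` paints each cell as a filled 1.29 µm² ellipse
(aspect 2.5, long axis along the flow) into the channel of its lineage
label, then blurs (σ = 0.25 µm), adds a background plane with a linear
gradient, and adds Gaussian noise. The ground-truth masks are the
pre-blur, pre-noise labelings, so segmentation accuracy can be scored
exactly; truth is invariant to the noise seed. The default pixel size,
0.1791 µm, is back-derived from the equivalence 1.29 µm² ≈ 40.2 px and is
an inference, not a measurement — it is what makes the pipeline's
15-pixel and 200-pixel thresholds physically meaningful on synthetic
data. Rasterization marks a pixel as cell when at least half of it is
covered (5×5 subsampling); per-cell pixel counts then quantize to
40 ± 2 px depending on subpixel phase, and summed truth areas stay within
2 px per cell of the continuum value. The renderer deliberately omits
optical PSF physics, photobleaching, stage drift, shot-noise statistics
(a Poisson mode would be a straightforward extension) and stitching; the
point is a controllable ground truth, not camera realism.

`make_fixture()` provides seed-pinned toy images (documented in its help
page) that pin down every pipeline semantic separately: the 6 px vs 20 px
gap pair for closing, a chessboard with exactly known cross-color
spacing, a >80% coverage field for the gate, and a blank for the
false-positive control.

## Quantification pipeline

`segment_channel()` uses a local-mean adaptive threshold: foreground is
intensity above the local mean (box neighbourhood, ~1/16 of the image
side, replicated borders) by $(1-s)\,A/2$, where $A$ is the robust signal
amplitude (99.9th percentile minus median) and the sensitivity $s$ is a
piecewise-linear function of the median intensity (defaults 0.5 rising to
0.65), as is the fraction of dimmest pixels removed as background
(0–10%). The original calibrations of these two mappings are not
recoverable from any published description, so the defaults are declared
approximations, chosen so that measured coverage tracks ground-truth
coverage within a few percent on default renders. Two guards matter in
practice: a noise floor of three robust standard deviations of the local
residual (otherwise pure-noise images segment into spurious ≥15 px
clusters — the blank-image control requires < 0.5% coverage), and a
constant-intensity escape hatch that returns an empty result with a
warning rather than an arbitrary mask. Components are 8-connected,
objects under 15 px (the minimal footprint of a vertically standing cell)
are discarded, and border-touching objects are retained.

Downstream measurements follow fixed semantics:

* **Coverage** — OR-merge of the two channel masks, occupied fraction.
* **Colony areas** (`colony_areas()`) — images above 80% coverage are
  excluded (clusters are indistinguishable there); otherwise objects
  < 200 px (≈ 5 cells) are removed *first*, then the mask is closed with
  a disc of radius 5 px, then component areas are reported in µm² with
  their median. Filter-then-close is the default ordering; the reverse is
  available behind a flag for sensitivity analysis.
* **Cross-lineage mixing** (`cross_lineage_mixing()`) — each channel is
  closed separately, object centroids extracted, and nearest-neighbour
  distances to the *other* color pooled from both directions. By default
  no 200 px filter is applied before mixing (the closing step is the only
  documented preprocessing for it); passing `min_colony_px = 200` gives
  the alternative reading. Empty channels make mixing *undefined*,
  reported as missing rather than zero. `mixing_from_table()` computes
  the same statistic directly from simulated cell tables (lineage groups
  as colonies), providing the ground-truth side of the image-vs-truth
  recovery check (agreement within 15% on default renders).
* **Attachment events** (`detect_attachment_events()`) — an event is a
  new object persisting at the same location (within ε = 3 px, an
  unprinted tolerance) for ≥ 3 consecutive frames, recorded at the first
  frame of its run; greedy nearest-centroid linking, uniform frame
  intervals required. `attachment_rate()` is the OLS slope of cumulative
  count versus time, and `attachment_probability()` normalizes it by the
  through-flux, $p_\mathrm{att} = r/(QC)$, refusing inconsistent inputs
  with $r > QC$.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to finish in minutes on one core while keeping every
statistical check adequately powered: transport batches of
$2\times10^4$–$10^5$ particles ($10^5$ for reactivity recovery, which
lands within 10%); colonization runs with 400 founders on a
1 cm × 250 µm floor quantified in a 250 µm window 9 mm downstream, 10–20
seeds per condition for trend tests. Every stochastic stage takes an
explicit seed, and per-stage seeds are derived deterministically from one
master seed (`run_replica()`), so identical configurations reproduce
identical outputs bit for bit.

## Known limitations

* No steric interactions or lateral colony spreading; clonal colonies are
  quasi-1-D comets with correspondingly small rendered areas (see above).
* The reaction-limited capture model collapses all adhesion biology into
  one reactivity; diffusion-limited or intermediate regimes are refused
  analytically and only reachable by simulation.
* Swimming is isotropic diffusion: no run-and-tumble correlation times,
  chemotaxis, hydrodynamic wall attraction, or cell-shape effects.
* The renderer's noise is Gaussian and additive; segmentation calibration
  against real camera statistics would need re-tuning of the sensitivity
  and background mappings.
* Passing the synthetic-recovery checks demonstrates internal consistency
  of simulator + renderer + pipeline; it does not validate the pipeline
  against real micrographs, for which no public ground truth exists.
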