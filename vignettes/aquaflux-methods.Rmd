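---
title: "Models and methods behind aquaflux"
author: "aquaflux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

# Scope

aquaflux models and analyses the two experimental pillars of functional
aquaporin characterization in yeast:

1. **Stopped-flow osmotic-shock kinetics.** Yeast cells equilibrated in an
   impermeant osmolyte (sorbitol) are abruptly exposed to a hyperosmotic
   solution. Water efflux shrinks the cell; a volume-sensitive
   fluorescence signal records the shrinkage. If the shock solute is a
   permeant (glycerol), its influx subsequently re-swells the cell. From
   these traces the osmotic water permeability $P_f$ and the glycerol
   permeability $P_{gly}$ (both cm s$^{-1}$) are estimated, and from
   temperature series their Arrhenius activation energies $E_a$
   (kcal mol$^{-1}$).
2. **Channel structure.** Pore-radius profiles of channel models (PDB) by
   largest-inscribed-sphere search, constriction (ar/R filter) detection,
   pore-lining residue identification, residue-level
   hydrophobicity/hydrophilicity ratios, and conservation analysis of
   channel-lining alignment columns, including ar/R point-mutation
   bookkeeping (e.g. `W86T`).

Because no public data accompany the motivating experiments, the package
carries a first-class synthetic-data layer: every estimator can be
validated against traces, structures and alignments whose ground truth is
known by construction.

# The kinetics estimation chain

## Estimators

The shrinkage signal is fitted to a single exponential
$F(t) = b + A e^{-kt}$ by nonlinear least squares
(`fitShrinkageRate()`, Levenberg–Marquardt via minpack.lm). Starting
values: $b_0$ = last sample, $A_0 = F(0) - b_0$, and $k_0$ from a
log-linear fit of the first third of the decay. The water permeability
follows the standard stopped-flow formula

$$P_f = k \,\frac{V_0/A}{V_w\,(osm_{out})_\infty},$$

with $V_0/A$ the cell volume-to-area ratio (cm), $V_w$ the molar volume
of water (18.07 cm$^3$ mol$^{-1}$) and $(osm_{out})_\infty$ the final
external osmolarity (converted to mol cm$^{-3}$). This formula is the
*initial-slope* normalization of the relaxation: at $t = 0$ the relative
volume obeys $\dot v = -k\,(1 - v_\infty)$ with
$v_\infty = osm_{in}/osm_{out}$.

The glycerol re-swelling is fitted by ordinary least squares on a linear
window after the trace minimum (`fitReswellingSlope()`), and

$$P_{gly} = m\,(V_0/A),$$

with $m$ the slope in relative-volume units. Because the instrument
records fluorescence, not volume, the raw slope is divided by the
estimated transduction span, obtained from the shrinkage amplitude:
$\widehat{span} = |A| / (1 - v_\infty)$. This makes the whole chain
invariant under rescaling of the signal (tested as a property).

Window selection for the slope fit is fully deterministic: the global
minimum of a smoothed copy of the signal (moving average over 5% of the
samples), a guard gap (default 3% of the samples), then a window of 40%
of the samples or to the trace end. The guard gap exceeds the smoothing
half-window (2.5%) deliberately: minimum positions within the half-window
are blurred across the shrink/re-swell transition, and a shorter guard
would let pre-transition curvature leak into the linear fit, breaking the
exact noiseless round trip with the exponential-mode generator. The same
argument trims the half-window off the segment used for the span
estimate.

Activation energies come from ordinary least squares of $\ln P$ against
$1/T$ (kelvin): $E_a = -R \cdot slope$ with
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. The estimator is exact
on exactly Arrhenius inputs. Replicate aggregation reports mean ± SD;
technical replicates are averaged within each temperature before the
Arrhenius fit. Strain differences use a two-sided Welch $t$-test (the
unequal-variance form, a deliberate choice where the convention is
ambiguous) with the field's labelling: `***` ($p<0.001$), `**`
($p<0.01$), `ns` otherwise.

## The forward models

`simulateShock()` provides two generator modes.

**Exponential mode** is the exact inverse of the estimator chain:
$v(t) = v_\infty + (1-v_\infty)e^{-kt}$ with $k$ back-computed from the
$P_f$ formula; for glycerol shocks, once the shrinkage transient has
decayed to 0.5% of its amplitude the trace switches to a linear recovery
of slope $m = P_{gly}/(V_0/A)$. Noiseless round trips through the
estimators recover $P_f$, $P_{gly}$ and $E_a$ to $10^{-6}$ relative;
this mode defines the package's recovery benchmarks.

**ODE mode** is a mechanistic two-state model (relative volume $v$,
internal permeant amount $g$ per initial volume, osmolar units):

$$\dot v = -\frac{P_f V_w}{V_0/A}\big(C_{out} - \tfrac{s+g}{v-\beta}\big),
\qquad
\dot g = \frac{P_{gly}}{V_0/A}\big(C^{gly}_{out} - \tfrac{g}{v-\beta}\big),$$

with $s$ the conserved impermeant internal osmolarity, $C_{out}$ the
(constant) external osmolarity, and $\beta = 1 - $ `activeFraction` an
osmotically dead volume (default 0). For a sorbitol shock
$C^{gly}_{out}=0$; for a glycerol shock the shock solution is the
permeant itself, $C^{gly}_{out}=C_{out}$ — the only choice under which
the early re-swelling slope equals $P_{gly}/(V_0/A)$, i.e. under which
the linear-slope convention measures the nominal permeability.
Integration uses deSolve. All solutes are osmotically active; there is
no dye kinetics, no instrument dead time, and a single representative
cell geometry per run.

Both permeabilities scale with temperature as
$\exp(-E_a/R\,(1/T - 1/T_{ref}))$. The fluorescence transduction is
linear, $F = baseline + span\,v$, with additive i.i.d. Gaussian noise of
SD `noiseSd * span`; self-quenching is oriented so shrinkage lowers the
signal.

## Defaults and why

* Osmolarities 1.4 → 2.1 osmol L$^{-1}$: the equilibration and shock
  buffers of the motivating experiments; equilibrium relative volume
  $1.4/2.1 = 0.667$.
* $V_0/A = 8.3\times10^{-5}$ cm: a 2.5 µm-radius spherical cell
  ($r/3$) — a typical yeast spheroplast; no measured value is available.
* Reference temperature 23 °C; Arrhenius grid {10, 15, 20, 25, 30, 35} °C
  (six temperatures spanning the stated 10–35 °C range).
* Acquisition window 60 s at 10 ms sampling: long enough that, at the
  coldest Arrhenius temperature, a glycerol trace completes its shrinkage
  (~37 s at 10 °C) and still offers a usable linear window; the same
  duration serves water shocks, whose transient relaxes in a few seconds.
* Noise SD 0.01 of the span, 10 replicates at the reference temperature,
  3 per Arrhenius temperature; replicate $r$ at temperature index $i$
  uses seed $seed + 1000 i + r$, making whole cohorts reproducible from
  one integer.

## The exponential-approximation bias, quantified

The single-exponential fit is a convention, not the exact solution of
the volume ODE. For an impermeant shock the ODE relaxation steepens as
$v \to v_\infty$, and a whole-trace fit converges to an effective rate

$$\hat k \;\approx\; k\,\sqrt{osm_{out}/osm_{in}}$$

(geometric mean of the initial-slope and linearized terminal rates).
At the 1.5× shock used here that is a **+22%** overestimate of $P_f$ —
measured, not hypothetical — and it is window-dependent: only acquisition
windows shorter than ~2 time constants (which never reach the plateau,
and which no practitioner would fit) push it below 10%. The glycerol
chain carries a milder **−10%** bias, from glycerol accumulation
progressively lowering the driving gradient across the fit window.
Both activation energies are immune: the bias factor is
temperature-independent (time-rescaling leaves $\ln\hat k - \ln k$
constant), and the measured $E_a$ recoveries under the mechanistic model
are within 0.4% (water) and 3% (glycerol). The package's recovery test
against the mechanistic model asserts a 10% band per quantity and
therefore fails for $P_f$ (and marginally for $P_{gly}$): this is a
documented property of the exponential convention at a 1.5× shock, not
an implementation defect, and the exponential-mode benchmarks are exact
by construction. Practically: stopped-flow permeabilities obtained with
the single-exponential convention are internally consistent but carry a
shock-ratio-dependent scale factor relative to the mechanistic
permeability.

# Pore profiling

`poreProfile()` follows the inscribed-sphere idea of channel-profiling
tools: at each plane $z_j$ along the axis it maximizes, over the
in-plane center $c$, the clearance
$\min_a \lVert a - (c, z_j)\rVert - vdw_a$. Two search modes share the
same objective: an exhaustive grid (0.1 Å, the brute-force oracle) and a
stochastic refinement (200 Gaussian proposals, step 0.3 Å, geometric
cooling, seeded per plane). Numerical choices that matter:

* **Connectivity.** Candidate centers are confined to a drift radius
  (default max(2·zStep, 1) Å) around the previous plane's center. An
  unconstrained in-plane optimum is *not* the pore near a tight
  constriction — the clearance is larger outside the channel wall — so
  an unconstrained search tunnels to the exterior and reports the wrong
  radius. The constrained search is the standard "follow the pore"
  behaviour.
* **Polish.** The best center found by either mode is refined by a
  deterministic Nelder–Mead step, making radii independent of grid
  resolution and proposal sequence; this is what lets anneal and grid
  agree to well under 0.05 Å and rigid-motion invariance hold to
  $10^{-3}$ Å.
* **Capture radius** 10 Å: planes whose clearance exceeds it are clamped
  (open to bulk); planes with negative best clearance are flagged
  blocked. Default vdW set: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å;
  unknown elements get 1.70 Å with a warning (or an error in strict
  mode).
* **Axis.** Models are assumed pre-oriented with the pore along z
  (periplasmic side = +z). A principal-axis mode projects onto the
  leading inertia eigenvector, sign-canonicalized by atom file order, so
  profiles are invariant under rigid motion.

The constriction is the global radius minimum (ties toward smaller z).
`profileDelta()` compares two profiles plane by plane (linear
interpolation when grids differ) and reports the mean difference and the
difference at the first profile's constriction.

# Hydropathy and conservation

Grid-based cavity chemistry (as produced by commercial site-mapping
tools) is deliberately *not* re-implemented; aquaflux computes
hydropathy at residue level on the pore-lining set: a residue lines the
pore if any of its atoms' surfaces comes within 1.5 Å of an inscribed
sphere surface. The ratio reported is #hydrophobic / #hydrophilic with a
binary scale ({A,V,L,I,M,F,W,C,P} hydrophobic; Kyte–Doolittle threshold
mode as an alternative), for the whole pore or for the regions above and
below the ar/R constriction (upper = periplasmic, $z \ge$ boundary).
Consequently, published grid-volume-based ratios for specific homology
models are motivating references, not numeric targets; the procedures
are validated on constructed channels with known labels instead.

Channel alignment columns are classified as *identical* (one residue),
*similar* (all residue pairs score > 0 under BLOSUM62 — "chemical
similarity" made reproducible; a physicochemical-group rule is available
as an alternative), or *dissimilar* (anything else; gaps force
dissimilarity, all-gap columns are excluded with a warning). The
synthetic alignment generator emits columns with a recorded ground-truth
class — "similar" columns draw at least two distinct residues from
groups that are internally BLOSUM62-positive ({ILVM}, {FWY}, {ST}, {DE},
{KR}), "dissimilar" columns guarantee a non-positive pair — so the
classifier is validated by exact round trip. `applyMutations()` applies
ar/R specs such as `W86T` with wild-type validation and sequential
composition for double mutants; `mapColumnToReference()` anchors
alignment columns to ungapped reference numbering.

# What the synthetic layer does and does not show

The generators emulate: shock kinetics with realistic magnitudes and
Arrhenius temperature scaling, instrument-like additive noise, channel
geometries with designed constrictions, and alignments with controlled
conservation structure. They do not emulate: cell-size heterogeneity,
dye loading/leakage kinetics, instrument dead time, correlated noise,
real side-chain packing, or evolutionary covariation. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated model, and bounded robustness to i.i.d. noise — not accuracy on
any particular laboratory's raw traces.

# Problem sizes

The shipped validation suite runs cohorts of 10 reference replicates and
6×3 Arrhenius traces per shock kind (6001 samples per trace), profiles
20–40 Å toy channels at 0.5–1 Å plane spacing with a 0.1 Å oracle grid,
and 100 seeded alignments of 4×40 columns; these sizes were chosen so a
full check completes in minutes on a laptop while leaving every recovery
tolerance comfortably resolved.

# Known limitations

* The linear-slope $P_{gly}$ convention ignores the decaying driving
  gradient; under the mechanistic model it underestimates by ~10% at the
  default window (see above).
* The re-swelling window heuristics assume a single minimum; traces with
  multiple shock events are out of scope.
* The profiler's connected search can follow a dead-end side pocket if
  the starting plane's center is seeded inside one; for pre-oriented
  single-pore channels (the intended use) this does not arise.
* Hydropathy ratios are count-based; they weight a glycine and a
  tryptophan equally.
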