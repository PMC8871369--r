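---
title: "Modelling and measuring prozone inhibition of membrane PKA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring prozone inhibition of membrane PKA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkaprozone)
```

## The system

Protein kinase A (PKA) is held inactive as a holoenzyme: two catalytic
subunits (PKA-C) bound to a regulatory-subunit (PKA-R) dimer, with two
cAMP-binding sites per PKA-R. cAMP binding releases PKA-C, the canonical
activation event. Because PKA-R simultaneously binds both the activator
(cAMP) and the enzyme (PKA-C), it behaves like a bivalent linker — and
linkers show prozone behaviour: at low abundance they assemble productive
complexes, at high abundance they titrate their partners into incomplete
complexes. `pkaprozone` models what happens when PKA-R is acutely recruited
to the plasma membrane (by rapamycin-induced FKBP–FRB dimerisation), and
reimplements the single-cell image-analysis procedures used to measure the
consequences with a membrane-targeted FRET activity reporter, both in
dishes and in a microfluidic gradient device.

## The protomer partition-function model

The membrane compartment is a well-mixed pool of independent PKA-R
*protomers*, each with one PKA-C site and two cAMP sites. A protomer
microstate is $(c, a)$ with $c \in \{0,1\}$ bound catalytic subunits and
$a \in \{0,1,2\}$ bound cAMP. Its statistical weight relative to the empty
protomer is

$$w(c,a) = \left(\frac{C_f}{K_C}\right)^{c} \binom{2}{a}
\left(\frac{A_f}{K_A}\right)^{a} \alpha^{-ca},$$

where $C_f$ and $A_f$ are free PKA-C and cAMP, $K_C$ is the PKA-C
dissociation constant from a cAMP-free protomer, $K_A$ the per-site cAMP
dissociation constant on a PKA-C-free protomer, and $\alpha \ge 1$ the
allosteric coupling: each bound cAMP weakens PKA-C binding by $\alpha$
(and, by the thermodynamic cycle, vice versa). Treating protomers
independently keeps the state space at six microstates while preserving
the holoenzyme stoichiometry per protomer pair (2 PKA-C, 4 cAMP); no
cooperativity between the two protomers of a dimer is modelled.

Given conserved totals $(R_{tot}, C_{tot}, A_{tot})$, `solve_equilibrium()`
finds the unique free concentrations satisfying

$$C_f + R_{tot}\langle c\rangle = C_{tot}, \qquad
A_f + R_{tot}\langle a\rangle = A_{tot}.$$

Each conservation equation is strictly monotone in its own free variable,
so a nested bracketing bisection (outer loop on $A_f \in [0, A_{tot}]$,
inner on $C_f \in [0, C_{tot}]$, 90 halvings each) converges
deterministically; residuals land far below the $10^{-9}$ relative
tolerance asserted in the tests. Degenerate totals (zeros) return the
corresponding boundary state rather than erroring. cAMP is conserved by
default; `camp_mode = "buffered"` clamps $A_f = A_{tot}$ for users who
prefer to treat the cAMP pool as externally fixed — the data available do
not discriminate between the two, and conservation is the more cautious
choice because it lets translocated PKA-R titrate cAMP as well as PKA-C.

The activity readout is free catalytic subunit $C_f$. Translocation of an
amount $R_x$ of PKA-R adds $R_x$ protomers and co-recruits $\rho R_x$
catalytic subunits:

```{r}
curve <- activity_vs_R(seq(0, 10, length.out = 200))
glance(curve)
```

With the default parameters the curve is biphasic with a below-baseline
tail, which the test suite asserts rather than assumes.

### Default parameters and why

| parameter | default | meaning |
|---|---|---|
| `K_C` | 0.01 µM | tight holoenzyme: PKA-C on cAMP-free PKA-R |
| `K_A` | 0.1 µM | per-site cAMP affinity on free PKA-R |
| `alpha` | 100 | per-cAMP weakening of PKA-C binding (×10⁴ for 2 cAMP) |
| `R_basal`, `C_basal` | 0.1 µM | basal membrane pools |
| `A_tot` | 1.0 µM | membrane-local cAMP pool |
| `rho` | 0.5 | PKA-C co-recruited per translocated PKA-R |

`K_C`, `K_A` and `alpha` are generic order-of-magnitude values for a
high-affinity holoenzyme dissolved by cAMP loading. `A_tot` and `rho` were
chosen once so that the basal state sits on the rising (sub-optimal) limb
of the activity curve and the optimum lies within the translocation range:
the cAMP pool (1 µM, i.e. 0.5 µM of fully loadable protomer) caps how much
incoming PKA-R can be neutralised by cAMP, and partial co-recruitment
($\rho < 1$) is what makes the high-$R_x$ tail inhibitory — if every
translocated protomer carried its own catalytic subunit ($\rho = 1$), free
PKA-C would grow monotonically (roughly like $\sqrt{K_C C_{tot}}$) and no
prozone would occur. Physically, $\rho < 1$ reflects that a fraction of
the overexpressed regulatory subunit is free rather than
holoenzyme-bound.

## Translocation kinetics

Cytoplasmic depletion data show fast, dose-dependent membrane
accumulation (plateau within ~3 min at 100 nM rapamycin). The model
collapses the FKBP–rapamycin–FRB ternary-complex kinetics into one
exponential with dose-dependent plateau and rate through the same
fractional occupancy $E(d) = d^h/(d^h + \mathrm{EC}_{50}^h)$:

$$R_x(t) = R_{max}\,E(d)\,\bigl(1 - e^{-k_{max} E(d) t}\bigr).$$

Defaults: $\mathrm{EC}_{50} = 10$ nM, $h = 1$, $k_{max} = 1$ min⁻¹,
$R_{max} = 1$ µM. These make 2 nM sub-EC50 (slow, partial, near-optimal),
20 nM supra-EC50 (fast, overshooting the optimum) and 100 nM saturating
(≥ 90 % of plateau by 3 min — asserted in tests). Composing $R_x(t)$ with
the equilibrium model point-by-point assumes binding equilibrates much
faster than translocation (quasi-steady state); this assumption is stated,
not tested against a full kinetic model.

```{r, fig.width = 5, fig.height = 3}
autoplot(activity_timecourse(20, seq(0, 60, by = 2)))
```

The activity → emission-ratio proxy is a saturating map
$r = DR\,[S(\mathrm{Act}) - S(\mathrm{Act}_0)]$ with
$S(x) = x/(x + K_{act})$. $DR$ defaults to 0.209, the biosensor's
calibrated full-scale fractional ratio increase under saturating
forskolin/IBMX stimulation. $K_{act} = 0.1$ µM is a package choice (no
measured value exists): the basal-activity scale, so that physiological
excursions use the informative part of the response curve. Only the shape
of the proxy depends on it; the full-scale calibration does not.

## The gradient device

Cross-channels of span $L$ connect a continuously replenished sink
($y = 0$) to a source ($y = L$); high hydraulic resistance suppresses
flow, so transport is diffusive and the steady state is affine,
$c(y) = c_{sink} + (c_{source} - c_{sink})\,y/L$. $L = 250$ µm is fixed by
the two printed operating points (0–20 nM at 0.08 nM/µm; 10–20 nM at
0.04 nM/µm), both consistent with this single span. A truncated
Fourier-series transient (`transient_profile()`, Dirichlet boundaries,
zero initial interior, terms kept until the decay envelope falls below
$10^{-9}$ of the concentration scale) is available for movie rendering;
the default diffusivity 300 µm²/s is a small-molecule scale and affects
nothing at steady state.

`predicted_cell_profile()` samples the local dose at 20 positions along a
cell span (default 50 µm, static) and runs the composed model at each
position; positions are normalised with 0 at the source-facing
(high-rapamycin) end. In a steep gradient the high end transiently leads
(faster translocation on the activating limb) and is later suppressed the
most, flipping the internal activity gradient — the mechanism behind the
migration reversal. `polarity_score()` is front-half minus rear-half mean.

## Image analysis

The pipeline mirrors standard biosensor practice: threshold segmentation
(8-connected components, < 50 px discarded, deterministic centroid
ordering), per-pixel dark-corrected ratio `(FRET - DF)/(CFP - DF)` with
non-positive denominators masked, mask-mean ratios with an
expression-level exclusion filter, cytoplasmic tracking by eroding the
outermost 20 pixels (7.78 µm at the default 0.389 µm/px — the pixel pitch
is itself derived from that printed pair) and averaging strictly positive
pixels, nuclear-centroid tracking in the marker channel (y-displacement
only, +y toward the source; missing frames flagged, never interpolated;
multiple components resolved to the largest with the event logged), 20-bin
intracellular profiles over the mask's bounding extent, and per-time
mean/SEM with a two-tailed pooled-variance Student's *t*-test.
Zero-variance identical groups return $t = 0$, $p = 1$ by an explicit
guard. Everything here is deterministic given its inputs.

Connected-component labelling and binary erosion are implemented in the
package (vectorised label propagation / 3×3 neighbourhood AND) because the
segmentation contract requires 8-connectivity throughout.

## The synthetic-microscopy generator

`render_movie()` draws cells (dish: 32-px-radius disks on a grid; chip:
channel-filling 20-px-wide, 128-px-long bodies with rounded caps and a
3-px membrane rim — dimensions chosen so the 20-px erosion test is
meaningful), gives each a truncated-lognormal expression scalar
(σ = 0.5, clamped to [0.4, 3], emulating the measured spread of PKA-R
levels without producing unsegmentable cells), imposes channel intensities
consistent with the model-driven (or explicitly imposed) ratio field, and
applies the camera model `dark + Poisson(signal) + Normal(0, read_sd)`
(defaults 100, shot noise on, SD 3). One seeded stream per scenario makes
output bit-identical for identical `(scenario, seed)`.

Migration is phenomenological: a 1D biased random walk (defaults
`v0` = 0.3 µm/min, `sigma_step` = 1 µm, initial upward fraction 0.8,
reflecting channel ends) whose polarity flips at a per-cell time
τ ~ U(15, 60) min in gradient scenarios (anchored to the ~15-min onset of
the intracellular response), never flips in controls, and is resampled
every 15 min under uniform 100 nM. These values are generator choices —
the source data do not quantify speeds or reversal-time distributions —
and must not be read as estimates of real cells.

What the generator does *not* emulate — stage drift, photobleaching,
spectral bleed-through, 3D optics, shape dynamics — bounds what passing
tests show: the pipeline is validated against its own stated contracts
(exact noise-free recovery; RMS ratio error < 0.01, depletion error < 3 %,
nuclear tracking ≤ 1 px at default noise), not against registration or
correction steps real drifted data would additionally need.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale: 12-cell dishes
(264×352 px, ~11 frames), 9–20-lane chips (643 rows), 48-cell track
populations over 180 min — sizes at which every behaviour under test is
already unambiguous. The equilibrium solver is pure bisection (no
randomness, no convergence failures for valid inputs; brackets guarded
anyway). The validation scenario for profile-sign recovery (`chip_ramp`)
imposes a ratio ramp of contrast $DR/2$ — half the biosensor's full scale,
comparable to the intracellular contrasts visible in calibrated ratio
maps — because the model-composed late-time contrast (~0.005 ratio units)
sits at the bin-noise floor and cannot support a sign-recovery criterion.

## Known limitations

* The partition-function model is a minimal realisation of the stated
  stoichiometry and titration mechanism; coefficient-level agreement with
  any particular measured dose–response is not claimed, only the
  qualitative predictions (biphasic curve, below-baseline tail, dose
  ordering of transient vs sustained responses).
* AKAP anchoring, phosphodiesterase/phosphatase dynamics, spatially
  resolved cAMP pools and PKA isoform differences are out of scope.
* Quasi-steady-state composition of translocation and binding is assumed.
* The migration model is descriptive, not mechanistic; its reversal rule
  encodes the observed phenomenology directly.
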