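---
title: "Modelling cell survival in droplet-based cell deposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell survival in droplet-based cell deposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellspray)
```

## The problem

Cell spraying, inkjet bioprinting and laser-assisted cell transfer all move
cells by ejecting them inside liquid droplets. When such a droplet lands, the
impact flattens the cell, stretches its membrane, and — beyond a critical
stretch — ruptures it. `cellspray` implements an analytical chain from the
impact parameters of a single cell-containing droplet to the probability that
the cell survives, and averages that probability over whole polydisperse
spray spectra, so that deposition settings (driving pressure, nozzle
distance, bio-ink viscosity, substrate stiffness) can be optimised rationally
instead of by trial and error.

## The model chain

The cell is a spherical liquid droplet with diameter $D_c$, viscosity
$\mu_c = 12$ mPa s, density $\rho_c = 1015$ kg m$^{-3}$ and effective surface
tension $\sigma_c = 0.072$ N/m. For one impact the chain is:

1. **Soft substrate → equivalent hard impact.** A substrate of stiffness
   $S \in [0,1]$ (liquid pool to glass) maps the droplet to an effective
   hard-wall impact: $D_\mathrm{eff} = (2-S)\,D_0$,
   $V_\mathrm{eff} = \tfrac{1+S}{2}\,V_0$ — the linear interpolation between
   the hard-wall identity at $S=1$ and the classical liquid-pool equivalence
   (twice the diameter at half the velocity) at $S=0$. Gelatin-coated
   substrates use $S = \min(1,\,C_1 C_g)$ with $C_1 = 5$, so substrates with
   more than 20% gelatin by mass count as hard.
2. **Maximal spreading.** With the cell Weber number
   $\mathrm{We}_c = \rho_c V^2 D_c/\sigma_c$, the maximal spreading ratio on
   a hard wall follows the capillary-regime law
   $D_{c,\max,0}/D_c = 0.9\,\mathrm{We}^{1/4}$ for $\mathrm{We} \ge 5$.
   Below $\mathrm{We} = 5$ a small constant deformation is assumed (the
   $\mathrm{We}=5$ value, $\approx 1.35$), which makes the law continuous at
   the threshold and the predictions velocity-independent in that regime.
   The same law, applied to the droplet's own Weber number, gives the
   droplet spreading $D_\max$. Outside the capillary validity regime
   ($\mathrm{We} > \mathrm{Re}^{4/5}$) a counted, non-fatal warning of class
   `cellspray_validity` is emitted.
3. **Deformation measure.** Volume conservation fixes the flattened cell's
   height $h = D_c^3/D_{c,\max}^2$; the deformation parameter is the
   Taylor-type ratio $M_0 = (D_{c,\max,0}-h)/(D_{c,\max,0}+h)$, which is 0
   for a sphere and tends to 1 for a plane.
4. **Cushioning by the surrounding droplet.** The carrier droplet absorbs
   part of the impact. We attenuate the deformation odds:
   $M = M_0 / \left(M_0 + (1-M_0)\,K\right)$ with strength
   $K = 1 + C_0\,(D_0/D_c - 1)/(1 + \mu_0/\mu_c)$ and $C_0 = 5$. Larger
   droplets cushion more; more viscous droplets cushion less (they transmit
   the impact into the relatively soft cell); a bare cell ($D_0 = D_c$) is
   uncushioned at any viscosity, and no finite cushioning prevents
   flattening in the $M_0 \to 1$ limit.
5. **Clamp.** The cushioned spreading
   $D_c^{(M)} = D_c\,((1+M)/(1-M))^{1/3}$ is clamped as
   $D_{c,\max} = \min(D_c^{(M)}, D_{c,\max,0}, D_\max)$: cushioning can only
   reduce spreading, and the cell never spreads beyond its droplet. A
   `clamp = "literal"` mode restricts the clamp to the latter two terms.
6. **Membrane stretch → survival.** The flattened cell is an oblate spheroid
   whose closed-form area $A$ gives the relative membrane area
   $\gamma = A/(\pi D_c^2)$, floored at 1 (compression does no damage). The
   survival probability is a linear ramp: certain survival below
   $\gamma_{cr} - \Delta\gamma$, certain death above
   $\gamma_{cr} + \Delta\gamma$, with $\gamma_{cr} = 1.5$,
   $2\Delta\gamma = 1$, hence $\eta(\gamma_{cr}) = 1/2$ exactly.

```{r single}
out <- predict_impact(D_0 = 39e-6, V_0 = 10,
                      fluid = fluid_properties(viscosity = 1.2e-3),
                      warn = FALSE)
out
```

### Equation transcription choices

Several display equations of the underlying model circulate only in typeset
form; this package fixes concrete functional forms and treats them as its
own design choices, constrained by the published anchors (the endpoints,
thresholds, constants and monotonicities restated above). In particular the
spreading prefactor 0.9 is the classical capillary-regime fit; the
deformation measure is the Taylor ratio (the standard drop-deformation
metric with the right sphere/plane endpoints and a closed-form inverse); and
the cushioning acts on the deformation odds rather than dividing $M_0$
directly, because a plain divisor would cap $M$ at $1/K$ and make
sufficiently large droplets immortal at any velocity, contradicting the
observed decay of viability with velocity for all droplet sizes. None of the
seven analytic anchor quantities recomputed by `scripts/acceptance.R`
depends on these reconstructed coefficients.

## Spray ensembles

A spray is a weighted set of $(D_0, V_0)$ observations. `predict_ensemble()`
evaluates the chain per droplet, bins the survival probabilities into a
relative-incidence histogram (20 uniform bins by default) and reports their
weighted mean as the expected post-spray viability. Droplets smaller than the
cell cannot carry one: by default they are excluded and the excluded weight
fraction is reported (`small_droplets = "bare_cell"` instead treats them as
bare-cell impacts, the most lethal reading). `viability_map()` and
`viability_contour()` produce the $(D_0, V_0)$ viability contours;
`parameter_sweep()` scans pressure, distance, viscosity or gelatin fraction.
Viscosity and gelatin act through the model only and reuse a fixed spectrum;
pressure and distance act through the spectrum itself.

```{r ensemble}
s <- generate_spray(spray_preset("reference"), n = 2000, seed = 1)
dist <- predict_ensemble(s, warn = FALSE)
dist
```

## The synthetic spray generator

Measured spray spectra are instrument-specific; the built-in generator is an
explicitly synthetic statistical stand-in that reproduces their structure:

* diameters are log-normal (right-skewed, highly polydisperse), median
  $30\,\mu\mathrm{m}\,(P_\mathrm{ref}/P)^{0.4}$ with $\sigma_{\log} = 0.5$,
  clipped to the 1–100 µm detection range — tens of microns at the reference
  pressure $P_\mathrm{ref} = 0.4\times10^5$ Pa, shrinking with pressure;
* velocities follow $12\,\mathrm{m/s}\,(P/P_\mathrm{ref})^{0.6}
  e^{-h/0.1\,\mathrm{m}}$ with 25% multiplicative Gaussian noise and a weak
  positive size–velocity coupling (exponent 0.15: small droplets decelerate
  faster in air) — of order 10 m/s at the reference distance $h = 3$ cm,
  rising with pressure and decaying with distance.

These coefficients were chosen once to place the reference preset in the
regime the measurements describe (droplets of tens of µm at up to tens of
m/s, expected viabilities spanning roughly 0.5–1 across the pressure series)
and are not fitted to any data. A green trend test therefore establishes
that the model plus a realistic spectrum reproduces the qualitative
pressure/distance/viscosity/stiffness trends — not that the generator
matches any particular nozzle. Real spectra drop in via
`read_droplet_table()`.

## Synthetic shadowgraphy and velocimetry

`render_pair()` simulates double-pulse shadowgraph exposures: dark disks on
a bright noisy background ($0.85 \pm 0.02$), displaced by $V\,\Delta t$
between frames ($\Delta t = 1\,\mu$s), with a Gaussian defocus edge of width
$1.5\,\mathrm{px}\cdot|z|/\delta_F$ ($\delta_F = 0.1$ mm). The blur width is
deliberately size-independent — the circle of confusion belongs to the
optics, not the particle — which keeps the sharpness gate, and hence the
measurement volume, the same for all droplet sizes.

`detect_droplets()` thresholds at half contrast, labels connected regions,
and sizes each candidate from its *integrated* intensity deficit, which is
conserved under defocus blur, with a small edge-width debias. The sharpness
score (maximum smoothed edge gradient over contrast) gates out droplets
beyond about one focal-plane thickness; detections outside 1–100 µm or
touching the border are discarded. `match_droplets()` pairs the frames
one-to-one, greedily over a displacement-plus-diameter-mismatch cost with a
downward-motion constraint and a displacement cutoff (the pulse delay is
chosen so matches are unambiguous, so the greedy pairing coincides with the
optimal one in practice). `characterize_spray()` chains everything into a
measured `spray_sample`.

Practical limits of the synthetic instrument: in-focus sizing is accurate to
well under 5% from 5 µm upward, but the edge-width debias over-corrects
below about 3 µm, so the effective detection floor is ~3 µm rather than the
nominal 1 µm; velocities are accurate to a fraction of a pixel per pulse
delay. The recovery tests (single droplet within 5%; 400-pair population
means within 10%) quantify exactly what the pipeline guarantees.

## Numerical choices and edge cases

* SI units everywhere internally; the CLI parses µm, mPa s, bar, etc.
* The oblate-area formula switches to a series in the eccentricity below
  $e = 10^{-4}$ to avoid 0/0 at the sphere limit; it matches a
  surface-of-revolution quadrature to $10^{-9}$ relative error.
* $M \to$ spreading is the exact closed-form inverse of the deformation
  definition; $M = 1$ signals a domain error (infinite spreading).
* The clamp never pushes the cell below its resting diameter (guarded
  explicitly; with the default constants the caps all exceed $D_c$).
* Spreading-law validity violations warn once per call with a count, never
  fail; at cell scale the capillary condition is violated for effective
  velocities above ~4 m/s, which is expected and informative, not an error.
* All stochastic components (`generate_spray()`, `render_pair()`,
  `characterize_spray()`) take explicit seeds and restore the caller's RNG
  state.

## Known limitations

The cell is Newtonian (no shear thinning), centred in its droplet (no edge
shear), and alone (no multi-cell droplets). The partial-survival ramp is a
population-level description, not single-cell mechanics. The generator and
the imaging noise model are synthetic stand-ins: green tests validate the
pipeline's internal consistency and qualitative trends, not any particular
spray hardware.
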