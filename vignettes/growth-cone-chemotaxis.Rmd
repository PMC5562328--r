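---
title: "Methods: an activator-inhibitor model of growth-cone chemotaxis and topographic mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activator-inhibitor growth-cone chemotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxmap)
```

## The model and its assumptions

A growth cone is modelled as a one-dimensional segment of length $L$
(default 10 um) with reflecting ends. Two intracellular species — an
activator A and an inhibitor I of the motility effector E — diffuse,
decay, and receive input from the transduced guidance-cue signal
$f(R, G(x))$:

$$\partial_t Z = D_Z \partial_x^2 Z - k_Z Z + c_Z + \alpha_Z f(R, G(x)),
  \qquad Z \in \{A, I\},$$

with $E(x) = A(x)/I(x)$ (a push–pull enzymatic readout) and migration
driven by the relative polarity $\Delta E / E^*$, i.e. the difference of E
across the cone scaled by its centre value — Weber–Fechner sensing, so
only *relative* asymmetry matters. The model is linear in each species;
its steady state under a linearised stimulus $f^* + g_{\mathrm{eff}} x$
is a cosine-mode series. Assumptions worth keeping in mind:

* **steady state**: transient responses (and phenomena such as axonal
  overshoot) are outside the model;
* **shallow gradient**: the closed-form polarity is the first-order term
  in $g_{\mathrm{eff}}$. `growth_cone_context()` warns (threshold
  `shallow_tol`, default 0.5 relative) rather than errors, because the
  reference stimulus for the profile presets is itself not small;
* **1-D geometry**: no cone shape or 2-D signalling;
* **deterministic signalling**: no receptor or channel noise.

The polarity decomposes exactly as
$\Delta E/E^* = \Delta A/A^* - \Delta I/I^*$, with
$Z^* = (\alpha_Z f^* + c_Z)/k_Z$ and
$\Delta Z = 8 g L^3 h(D_Z/k_Z) / (\pi^4 k_Z)$, where

$$h(s) = \sum_{n \ \mathrm{odd}} \frac{1}{n^2\,(n^2 s + (L/\pi)^2)}.$$

Only odd cosine modes survive the end-to-end difference; the sum starts at
mode 1. Two checks pin this down: $h(0) = \pi^4/(8L^2)$ makes the
diffusion-free limit collapse to the pointwise answer
$\Delta Z = g L / k$, and the reaction–diffusion integrator reproduces the
series profile to $\sim 10^{-5}$ relative error. The series prefactor of
the full profile is $2g/L$ (per mode weight $(L/n\pi)^2[(-1)^n - 1]$); we
re-derived it from the Green's function of the diffusion–decay operator,
as consistency with the end-difference formula and the integrator
requires.

## The two algebra modes

The closed-form response is exposed in two conventions. In the default
`"reduced"` mode the efficacy $\alpha_Z$ enters only through the baseline
$Z^*$:

$$\frac{\Delta E}{E^*} = \frac{8 g L^3}{\pi^4}
  \left[\frac{h(D_A/k_A)}{\alpha_A f^* + c_A}
      - \frac{h(D_I/k_I)}{\alpha_I f^* + c_I}\right].$$

This is the convention in which the pattern boundaries and the threshold
$\gamma$ below take their familiar printed forms. In `"physical"` mode the
gradient amplitude of the input term carries $\alpha_Z$ as well (the
numerators acquire factors $\alpha_A$, $\alpha_I$), which is what the
reaction–diffusion equations actually integrate. The two modes agree
whenever $\alpha_A = \alpha_I$ and always agree in sign at the
concentration extremes; between their respective zero crossings they can
disagree in sign (for the switch preset: crossings at $\approx 6.2$ vs
$\approx 20.9$ uM). Every result records its mode; oracle comparisons
against the integrator use `"physical"`.

## Response patterns, the BAR condition, and preferred concentrations

The response numerator is linear in $f$, so its sign at the two
concentration limits classifies the whole curve into four patterns:
unidirectional attraction, unidirectional repulsion,
repulsion-to-attraction, and attraction-to-repulsion (BAR). With
$\eta = h(D_A/k_A)/h(D_I/k_I)$, BAR holds exactly on
$c_A/c_I < \eta < \alpha_A/\alpha_I$. Classification uses these analytic
limits, never sampled grid endpoints, so it cannot be fooled by a narrow
evaluation range; exact boundary ties (sign 0) are deliberately broken
*away* from BAR, since the strict inequalities fail there. For receptors
with $\partial f/\partial G < 0$ (unbound-active), classification happens
in $f$-space and is mapped back to concentration space by the sign of
$\partial f/\partial G$, so patterns are always reported against ligand
concentration.

At the BAR zero crossing the transduced signal equals
$\gamma = (\eta c_I - c_A)/(\alpha_A - \eta\,\alpha_I)$, and
$f(R, G_{\mathrm{pref}}) = \gamma$ yields the preferred concentration per
transfer function: $\gamma$ (identity), $\gamma K/(R-\gamma)$
(bound-active, needs $R > \gamma$), $(K/\gamma)(R-\gamma)$
(unbound-active, needs $R > \gamma$), and
$(\gamma/R_c)(K + R_c + R)$ (competitive). For the competitive variant the
printed closed form in circulation divides rather than multiplies by the
bracket; solving $f = \gamma$ directly gives the multiplied form, which is
also the only one consistent with a preference that *rises* with receptor
level, and the numeric root finder confirms it to $10^{-9}$ relative.
We treat the divided form as a typesetting slip. Similarly, the
unbound-active transfer function is sometimes written $f(G)$ with the $R$
dropped from the argument list; it depends on $R$.

## Numerical choices

* **Series truncation**: 500 odd modes by default. Terms decay as
  $n^{-4}$ for $s > 0$ but only as $n^{-2}$ at $s = 0$, so a fixed
  relative-tail *error* threshold cannot be enforced uniformly; instead
  `h_series()` attaches an analytic tail bound and raises a
  `"chemotaxmap_tail"` *warning* when the bound exceeds `tail_tol`
  (default $10^{-6}$) of the partial sum. Tests near $s = 0$ raise
  `n_terms` to $10^5$–$10^6$. The exact closed form
  $h(s) = (\pi/L)^2[\pi^2/8 - (\pi^2\sqrt{s}/4L)\tanh(L/2\sqrt{s})]$
  (from the odd-mode partial-fraction identity) is exported as
  `h_closed()` and used as an independent oracle, never as the series
  implementation.
* **Profiles**: 201 grid points including both ends, $x = 0$ at the cone
  centre. Units: um, s, uM throughout; $\Delta E/E^*$ dimensionless.
* **Degenerate baselines** ($Z^* = 0$, e.g. the $c = 0$ profile presets at
  $G^* = 0$): a typed error naming the species, never infinities.
* **Root finding**: preferred concentrations by bisection on
  $\log_{10} G$ (100 iterations, i.e. to machine precision) bracketed by
  the sampled curve; closed forms are the default path.
* **Integrator**: Crank–Nicolson with four implicit-Euler startup steps
  (Rannacher smoothing — plain CN keeps stiff-mode ringing alive for the
  $D = 100$ presets), node-centred grid of 401 cells for $L = 10$,
  mirrored-ghost no-flux boundaries (second order), zero initial
  condition (the steady state of a linear system is unique, so the start
  only affects time-to-converge), steady when
  $\max|\partial_t Z|/Z^* < 10^{-8}$, horizon $60/k$. The explicit Euler
  scheme is retained for transparency and refuses to run when
  $\Delta t > \Delta x^2 / 2D$.

## Topographic mapping

Retinal receptor gradients are exponential,
$R(x) = R_0 e^{q x/\sigma}$, and tectal ligand gradients are
$G(x) = G_0 e^{-q(1 - x/\sigma)}$ (type 1, rostral–caudal) or
$G_0 e^{q x/\sigma}$ (type 2, medial–lateral). Reference values for
$q$, $\sigma$, $R_0$, $G_0$, $K$ are not published; the defaults
($q = 2$, $\sigma = 1$, $K = 1$, scales matched as $R_0 G_0 = \gamma K$
for type 1 and $G_0 = (K/\gamma) R_0$, or $(\gamma/R_c) R_0$, for type 2,
with $R_0 = 1000\gamma$ so every axon sits far above threshold) were
chosen once so the ideal map spans the full axis, and live in
`matched_gradients()` / the CLI config rather than buried in code.

No migration law is published either; the simulator's rule is the
package's own plumbing: explicit position updates
$x \leftarrow x + v_0 \tanh\!\big((\Delta E/E^*)/s\big)$ in the normalised
tectal coordinate, with $v_0 = 0.01\,\sigma$ per step, saturation scale
$s = 0.1$, stop tolerance $|\Delta E/E^*| < 10^{-6}$, at most $10^5$
steps, positions clamped to $[0, \sigma]$ with border pinning reported
rather than reflected. The rule is deterministic, bounded in speed, and
has its fixed point exactly at the response zero, matching the
steady-state argument for the terminal zone; with these scales terminals
agree with the analytic gradient inversion to $\sim 10^{-6}\sigma$ in the
shipped configurations. The cone senses the local linearisation
$G(X) + G'(X)x$ with the slope taken per normalised axis unit — i.e. the
axis is measured in units of the cone length. This is a deliberate scale
compression: a real tectum is two to three orders of magnitude longer
than a growth cone, and with a literal scale separation the response
near the terminal becomes so flat that any stopping rule placed at
$10^{-6}$ would fire far from the zero. Only the response *magnitude* is
affected; the zero crossing, and hence the terminal, is scale-invariant.

Map quality is summarised by a straight-line fit of terminal vs. source
position (slope, $r^2$) and by the local magnification
$dx_{\mathrm{tgt}}/dx_{\mathrm{src}}$, factored as
(source-gradient steepness) × (mapping-function steepness
$dG_{\mathrm{pref}}/dR$) × (inverse target-gradient steepness). For
type 1 the middle factor $-\gamma K/(R-\gamma)^2$ steepens as $R$ falls
toward $\gamma$; for type 2 it is constant — the two map families thus
distribute projection precision differently along their axes.

## The reference presets and their taxonomy

Six parameter columns ship in `inst/extdata/table1.yaml`: two profile
presets with stimulus ($L = 10$ um, $G^* = 10$ uM, $g = 0.75$ uM/um) that
realise attraction (`fig2C`) and its A/I-swapped repulsion twin
(`fig2D`), and four response-curve columns (`fig3B`–`fig3E`)
traditionally labelled repulsion-to-attraction, unidirectional repulsion,
unidirectional attraction, and BAR. The shipped values are kept exactly
as printed in the reference table. Classifying them with the model
itself, however, shows the printed table to be internally inconsistent
with two of the four traditional labels: columns `fig3B` and `fig3D` both
carry $c_A/c_I = 3000$, which forces repulsion at low concentration, so
no cone length or series convention can make `fig3D` unidirectionally
attractive, and `fig3C` sits on the far side of the
$\eta = \alpha_A/\alpha_I$ line ($\eta = 0.291$ vs. $0.25$), making it
attractive at both extremes. `preset_classification()` reports the stated
and computed pattern per column; the pattern-name aliases (`"bar"`,
`"repulsion_to_attraction"`, `"uni_attraction"`) bind to *computed*
patterns, and `"uni_repulsion"` — realised by no shipped column — errors
with an explanation rather than silently returning a mislabelled preset.
The anchor results are unaffected: `fig3B` and `fig3E` are exact A/I
swaps classifying as repulsion-to-attraction and BAR, with
$\eta = 0.29133$ strictly inside $(3.33\times 10^{-4}, 0.5)$.

```{r taxonomy}
preset_classification()
```

## The parameter sampler

`sample_parameters()` draws the eight kinetic constants log-uniformly
from $D \in [0.5, 100]$ um²/s, $k \in [0.5, 50]$ /s,
$c \in [0.01, 300]$ uM/s, $\alpha \in [0.1, 20]$ /s — the
order-of-magnitude envelope of the reference presets. Two hundred draws
realise all four response patterns in roughly comparable numbers, which
is what the property-based tests need; the draws emulate parameter
*diversity*, not measured biology. Passing tests on these draws shows the
algebra, classification and root finding are mutually consistent across
the parameter space — it does not validate the model against
experimental turning assays, receptor noise, 2-D cone geometry, or
axon–axon competition, all of which are out of scope.

## Problem sizes

The test suite and the acceptance script run with 500 series modes
(raised to $10^5$–$10^6$ only for the $s \to 0$ closed-form checks),
201–401-node integrator grids, a $101 \times 101$ phase-diagram scan,
15–21-axon maps, and 20–25-draw property loops — sizes at which every
check completes in seconds while keeping discretisation error well below
the asserted tolerances.
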