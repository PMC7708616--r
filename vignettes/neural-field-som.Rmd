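---
title: "Self-organizing maps driven by neural fields: model, stability and map quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing maps driven by neural fields: model, stability and map quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfsom)
```

## The model

`nfsom` simulates topographic map formation in a cortical sheet — the kind of
self-organization observed in area 3b of primary somatosensory cortex — with a
dynamic neural field in place of the hand-designed neighborhood function of a
Kohonen map. Two coupled equations evolve on a compact domain
$\Omega = [a,b]^q$ (the experiments use the unit square, $q = 2$):

* **Field dynamics.** The mean membrane potential $u(r,t)$ obeys an
  Amari-type integrodifferential equation
  $$\tau\,\partial_t u(r,t) = -u(r,t)
    + \int_\Omega w_l(|r-r'|)\,f_l(u(r',t))\,dr' + I(r,t),$$
  with lateral coupling the difference of an excitatory and an inhibitory
  Gaussian, $w_l(x) = K_e e^{-x^2/2\sigma_e^2} - K_i e^{-x^2/2\sigma_i^2}$,
  and $f_l = \operatorname{rect} = \max(\cdot, 0)$.

* **Learning.** Each lattice node carries a codebook vector $w_f(r,t) \in
  [0,1]^m$. The input drive is $I = 1 - |w_f - s(p)|_1/m$: nodes whose
  codebook already resembles the stimulus receive more drive, which makes the
  field's activity bump form around the best-matching unit. The codebook then
  follows an Oja-like rule gated by rectified field activity,
  $$\partial_t w_f(r,t) = \gamma\,(s(p) - w_f(r,t))
    \int_\Omega w_e(|r-r'|)\,f_e(u(r',t))\,dr'.$$
  Because the pull is always toward $s(p) \in [0,1]^m$, the codebook provably
  stays inside $[0,1]^m$; the training loop asserts this at every logged
  epoch.

Training is online: per epoch, one stimulus $p \sim U(0,1)^2$ is presented
(the mapping $s$ is the identity here — no receptor model), the coupled
system is integrated by forward Euler for a fixed horizon, and the field is
reset to its zero baseline. The generality hooks $f_l, f_e, f_s$ accept any
Lipschitz activation; the defaults above are the self-organizing-map
instantiation.

## Parameters and defaults

The defaults of `model_params()` and `experiment_config()` are the reference
conditions of the numerical experiments:

| parameter | default | meaning |
|---|---|---|
| $K_e, \sigma_e$ | 0.90, 0.1 | excitatory amplitude / width |
| $K_i, \sigma_i$ | 0.86, 1.0 | inhibitory amplitude / width |
| $\tau$ | 1.0 | field decay constant |
| $dt$ | 0.015 | Euler step |
| $t$ | 25.0 | integration horizon per epoch |
| $\gamma$ | 0.002 | learning rate |
| epochs | 7000 | stimuli presented |
| grid | $40 \times 40$ on $[0,1]^2$ | discretization $\Omega_d$, nodes at $i/40$ |
| init | $U(0, 0.01)$ | codebook initialization |

`dt` and `t` are treated as the same time unit, so an epoch integrates
$\lfloor 25 / 0.015 \rfloor = 1666$ steps. (Reading `dt` in milliseconds
against `t` in seconds would be inconsistent with $\tau = 1$ driving visible
transients within an epoch; the single-unit reading reproduces the reference
behavior.) The unstable demonstration differs only in the gains:
$K_e = 3.0$, $K_i = 2.80$.

## Stability conditions

The central theoretical objects are two sufficient conditions for local
exponential stability (in spatial $L_2$ norm) of the equilibrium
$(u^*, w_f^* = s(p))$, where $u^*$ solves
$u^*(r) = 1 + \int_\Omega w_l(|r-r'|)\operatorname{rect}(u^*(r'))\,dr'$:

1. **Kernel-norm condition**: $\bar w_l = \big(\int_\Omega\!\int_\Omega
   w_l(r,r')^2\,dr'dr\big)^{1/2} < 1/\ell_l$ with $\ell_l$ the Lipschitz
   constant of $f_l$ (1 for rect). For the Gaussian-difference kernel on a
   square, $\bar w_l^2$ has the closed form
   $$K_e^2\,\xi_{a,b}(\sigma_e/\sqrt2) + K_i^2\,\xi_{a,b}(\sigma_i/\sqrt2)
     - 2K_eK_i\,\xi_{a,b}\!\Big(\tfrac{\sigma_e\sigma_i}
     {\sqrt{\sigma_e^2+\sigma_i^2}}\Big),$$
   where $\sqrt{\xi_{a,b}(\sigma)}$ is the Gaussian double integral over
   $[a,b]^2$, expressible through the error function (`xi_ab()`). Stability
   is predicted while this value stays below 1 — the regime of balanced
   excitation and inhibition.
2. **Sufficient excitation**: $\inf_r \int_\Omega w_e(r,r')
   f_e(u^*(r'))\,dr' > 0$, i.e. the equilibrium keeps the learning gate open
   everywhere.

`stability_report()` evaluates everything at once:

```{r}
stability_report(kernel_spec(0.90, 0.1, 0.86, 1.0), spatial_grid(40))
stability_report(kernel_spec(3.0, 0.1, 2.80, 1.0), spatial_grid(40))
```

The stable parameter set gives a condition value of about 0.49, comfortably
below 1; the strong-gain set gives about 5.19, far above, and its training
runs never settle — the distortion trace oscillates over a several-fold
range as the map is repeatedly disrupted. Both the closed form and a lattice quadrature are reported: they
agree to well under 2% at this resolution, and since the reference value of
this quantity in the literature is quoted loosely (0.47 / 5.25, an
unspecified discrete evaluation), having both conventions available matters
for comparisons.

Erf appears twice: everywhere by default through the exact normal-CDF
identity $\operatorname{Erf}(x) = 2\Phi(x\sqrt2) - 1$, and additionally as
the classical fourth-degree rational approximation (`erf_rational()`,
absolute error $\le 5\times10^{-4}$), retained because the closed-form
condition is often quoted with it; it is used only as a cross-check variant.

## Map-quality metrics

* **Distortion** `distortion()`: mean squared distance from each sample to
  its nearest codebook vector — the vector-quantization loss. Along training
  it is logged against all stimuli seen so far; final values are against the
  full sample set. For a well-unfolded $40\times40$ map on the unit
  square it settles at a few times $10^{-3}$ rather than zero: boundary
  shrinkage keeps codebook vectors away from the domain edge.
* **Distance cloud** `dxdy_cloud()`: all pairwise codebook distances
  ($\delta x$) against the corresponding lattice distances ($\delta y$).
  Euclidean distances on both axes.
* **Performance index** `performance_index()`: compares the line through
  the origin and the cloud centroid (slope $\overline{\delta x} /
  \overline{\delta y}$) with the no-intercept least-squares fit (slope
  $\sum \delta x\,\delta y / \sum \delta y^2$), as the root-mean-square
  gap $\mathcal{P} = |s_{\mathrm{ref}} - s_{\mathrm{fit}}|
  \sqrt{\frac1k\sum_i x_i^2}$ over abscissae $x_i$ evenly spaced on
  $[0, \max\delta y]$. Only the two slopes are intrinsic to the cloud; the
  mean (rather than a sum) over abscissae keeps $\mathcal{P}$ independent
  of how many evaluation points are used (`k_eval`, default one per node),
  so values are comparable across lattice sizes. $\mathcal{P} = 0$ exactly
  when the codebook equals the lattice.

## Numerical choices

* **Coupling convention.** The lateral interaction term can be discretized
  two ways, and the package makes the choice explicit
  (`model_params(coupling = )`). Under `"integral"` the node sums are
  weighted by the cell measure $((b-a)/n)^q$ — the exact quadrature of the
  continuous equations, the convention under which the stability theory,
  the equilibrium solver and the Lyapunov functional apply verbatim. Under
  `"network"` (the default for training, matching the reference
  simulations and the plain-FFT implementations this model family comes
  from) the raw node sums are used, making the lateral coupling stronger
  by the reciprocal cell measure $(n/(b-a))^q$ — a factor $k$ on the unit
  square. The difference matters enormously for map formation: with
  integral coupling at the reference parameters the field is only weakly
  competitive, the activity bump is broad and shallow, and the codebook
  never breaks symmetry — training leaves it collapsed near the stimulus
  mean even after 7000 epochs. With network coupling the strong lateral
  inhibition produces a selective bump around the best-matching unit and
  the map unfolds within a few hundred epochs. Analysis functions that
  discretize the theory (`lateral_convolve()`, `equilibrium_field()`,
  `check_condition10()`, `lyapunov_value()`, the quadrature side of the
  stability report) always use the integral convention.
* **Convolution.** `lateral_convolve()` uses zero-padded (linear, not
  circular) FFT convolution: the integral runs over the compact domain only,
  and wrap-around would couple opposite edges of the sheet. The compiled
  training engine evaluates the same sum through the separability of the
  Gaussian (two small matrix products per kernel); both paths agree to
  $10^{-13}$ and are tested against the naive $O(k^2)$ double sum.
* **Integration order.** Within a step the field is advanced first using the
  previous codebook's drive, then the codebook using the freshly updated
  field; drive is recomputed every step from the evolving codebook (it
  changes within an epoch). At $dt = 0.015$ the ordering effect is far below
  solver tolerance.
* **Equilibrium.** `equilibrium_field()` iterates the fixed-point map from
  $u \equiv 1$; under the kernel-norm condition this is a contraction with a
  unique equilibrium. Default tolerance $10^{-11}$ in sup norm; an
  independent semismooth-Newton solve agrees to $10^{-9}$ in the tests.
  Outside the contraction regime the function warns and may legitimately
  fail; `stability_report()` then returns an `"undetermined"`/
  `"not_guaranteed"` verdict rather than inventing one.
* **Divergence.** A field exceeding $10^6$ (or going non-finite) aborts the
  epoch with a structured `nfsom_blowup` condition carrying the epoch and
  step; `train_som()` converts it into a flagged partial fit so sweeps can
  record the failure and continue. The reference unstable parameters do not
  blow up — the field stays bounded while the *learning* fails to settle —
  but stronger gains do.

## What the synthetic stream does and does not emulate

The stimulus generator draws i.i.d. uniform points on $[0,1]^2$ and the
codebook initialization from $U(0, 0.01)$, reproducing the reference
experimental conditions exactly (one seed determines initialization and the
whole stream; the published experiment seeds are 10, 74, 433, 721, 977,
1330, 3433, 5677, 9127, 7659). This exercises map formation from a
near-collapsed start under a stationary, uniform input distribution. It does
not emulate: structured or non-stationary input statistics, the
skin-receptor mapping $s$ of the biological model (identity here), sensory
noise, or lesion/reorganization protocols. Passing tests therefore
demonstrate correct dynamics and stability classification under the
reference conditions, not robustness of map formation on real sensory data.

## Problem sizes used by the test suite

Desk-scale checks run on $6\times6$ to $16\times16$ grids with short
horizons. The two end-to-end regime checks run at the full reference scale
($40\times40$, 7000 epochs, $t = 25$) with a single published seed (10);
running all ten seeds reproduces the reference spread but adds nothing
qualitative. A full run integrates about 11.7 million Euler steps and takes
a few minutes with the compiled engine. The desk-scale profile behind
`run_experiment(..., profile = "ci")` (16×16, 1500 epochs, $t = 5$) is
useful for smoke-testing a configuration end-to-end, but note that under
the network coupling the effective lateral strength scales with the node
count, so the stable/unstable boundary sits elsewhere at 16×16 than at
40×40 — desk-scale map quality is not a proxy for the full-scale regime
classification.

## Known limitations

* The stability conditions are sufficient, not necessary: a configuration
  violating them ("not_guaranteed") may still behave stably in simulation.
* $\mathcal{P}$'s absolute value depends on the abscissa convention; compare
  values only under the same `k_eval`.
* Under the integral coupling the reference learning rate does not form a
  map at all from the collapsed initialization (see the coupling paragraph
  above); conclusions about map quality are tied to the network convention.
* The theory's condition value is computed from the continuous integrals
  while the network-mode simulation scales the kernel by the node count;
  the stable/unstable classification carried by the condition (balanced vs
  strong gains) transfers, but the numeric threshold 1 should not be read
  as a statement about the network-mode coupling magnitude.
* Only $q \in \{1, 2\}$ domains are supported; the compiled engine covers
  $q = 2$ with the default activations, everything else falls back to the
  (slower) R integration path.
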