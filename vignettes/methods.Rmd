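---
title: "Model, estimators, and validation protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, estimators, and validation protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polcpm` implements an extended cellular Potts model (CPM) on a
two-dimensional hexagonal lattice in which each cell carries a
self-regulating per-site polarization field. This vignette documents the
model energetics, the non-obvious implementation conventions, the
observable estimators, and the scaled-down ("desk-scale") validation
protocols used in the test suite, including their known limitations.

## The model

Each lattice site holds an owner id (0 = empty) and a scalar
polarization $\epsilon(x, t)$. The configuration energy is

$$
H = \sum_{\text{cells}} \left[ \kappa_A A^2 + \kappa_P\, p_s^2 P^2 \right]
  - \sum_{\text{occupied } x} \epsilon_{\mathrm{eff}}(x)
  - B \cdot \#\{\text{cell–cell contact edges}\},
$$

with $A$ the cell area (site count), $P$ its perimeter, and
$\epsilon_{\mathrm{eff}}$ the polarization after any substrate penalty
$\phi \le 0$ is applied (`apply_phi_penalty()`). There is no reference
area: the equilibrium cell size emerges from the balance between the
contractile terms and the $-\epsilon$ gain per occupied site
(`equilibrium_area()` finds the discrete minimizer numerically).

Dynamics are Metropolis kinetics at $k_BT = 1$: one Monte-Carlo step
(MCS) attempts as many elementary source→target copy events as there are
directed boundary pairs at the start of the sweep, drawing uniformly from
the boundary-pair list. Because the proposal distribution depends on the
current boundary size, the acceptance includes a Hastings correction
$\log(B_{\text{now}}/B_{\text{after}})$ so that detailed balance holds
with respect to $H$ for the conservative part of the dynamics.

Two *dissipative* penalties enter the acceptance but not the state
energy: breaking a cell–cell contact costs $\Delta B$ per destroyed
contact edge, and losing substrate adhesion costs $D$ per lost occupied
site. `event_delta()` reports both `dH` (what the acceptance uses) and
`dH_state` (the exact difference of `total_energy()` before and after);
the test suite verifies `dH - dH_state` against an independent recount of
destroyed contacts.

### Polarization feedback

Accepted protrusions increment a regulatory accumulator $F$ on the
conqueror's sites within hex distance $R$ of the event and decrement it
on the loser's sites (retraction feedback). Once per MCS every occupied
site relaxes

$$
\epsilon \mathrel{+}= \mu\,(\epsilon_{\text{target}} - \epsilon),
\qquad
\epsilon_{\text{target}} =
\begin{cases}
\epsilon_0 + \Delta\epsilon/2 & F > 0\\
\epsilon_0 - \Delta\epsilon/2 & F < 0\\
\epsilon_0 & F = 0,
\end{cases}
$$

and $F$ is cleared. A conquered site inherits the conqueror's
$\epsilon$. The *specific polarizability* $\Delta\epsilon/\kappa_P$ is
the control parameter for single-cell motility and collective rotation.

### Perimeter-unit convention

On a hexagonal lattice a site edge has Cartesian length $1/\sqrt{3}$
when columns are unit-spaced. The perimeter energy uses contour length,
$\kappa_P (E/\sqrt{3})^2$ with $E$ the boundary edge count (equivalently
$p_s^2 = 1/3$), rather than raw edge counts. This choice
(`perimeter_unit = "contour"`, the default) is what reproduces the
reference motility onset at $\Delta\epsilon/\kappa_P \approx 500$;
`"edges"` is available for comparison and scales all perimeter energies
by 3.

### Cell cycle

Proliferating cells cycle through quiescence (phase 0), growth (phase 1)
and division (phase 2). A quiescent cell enters growth when its area
exceeds $A_T \cdot A_{\text{ref}}$ — this size threshold *is* the
contact-inhibition mechanism: crowded cells never reach it. During the
growth phase ($T_g$ MCS) the area stiffness is ramped down,
$\kappa_A^{\mathrm{eff}} = \kappa_A (1 - \tfrac{1}{2} c/T_g)$, with
$\kappa_P^{\mathrm{eff}} = \kappa_P \sqrt{\kappa_A^{\mathrm{eff}} /
\kappa_A}$, so the equilibrium area roughly doubles. The division phase
($T_d$ MCS) models mitotic rounding by $\Delta\epsilon \to 0$; the cell
then splits along a balanced connected bipartition and both daughters
restart quiescent, unpolarized ($\epsilon = \epsilon_0$, $F = 0$) with
base parameters.

## Observable estimators

* `msd()` / `vacf()` pool displacement pairs over replicates; headings
  are unit vectors of successive displacements, and zero-displacement
  samples are excluded pairwise rather than treated as direction zero.
* `fit_prw()` fits the two-dimensional Fürth form
  $\mathrm{MSD}(\tau) = 2 v^2 \tau_p [\tau - \tau_p(1 - e^{-\tau/\tau_p})]$
  by nonlinear least squares and flags non-convergence.
* `shape_metrics()` returns the gyration-tensor aspect ratio
  $\sqrt{\lambda_1/\lambda_2}$.
* `cell_stress()` is the virtual-dilation estimator
  $\sigma = 2\kappa_A^{\mathrm{eff}} A + \kappa_P^{\mathrm{eff}} p_s^2
  P^2 / A - \bar\epsilon$, i.e. the derivative of the cell energy with
  respect to a uniform dilation per unit area, **tension positive**. The
  $-\bar\epsilon$ term is an active "swim pressure": it grows exactly
  where cells polarize. In an expanding monolayer this cancels the
  mechanical stretch signal of the traction-bearing front cells, so the
  kymograph of the total stress does *not* show the expected
  edge-leading tension pattern. `tissue_kymographs(..., eps_rest =
  eps0)` therefore maps the *mechanical* part
  $\sigma_{\text{mech}} = \sigma + (\bar\epsilon - \epsilon_0)$, which
  does: leading-edge bins turn tensile before central bins and the
  tension ridge propagates inward (the X-shaped pattern).
* `burst_period()` extracts the growth-burst period from the spacing of
  the first few sharp rises of the mean-density series. Only the
  earliest bursts are used: the initial condition synchronizes the
  population, so the first waves are full doublings spaced by exactly
  $T_g + T_d$, while later waves are front-limited (the bulk is
  contact-inhibited), broadened, and delayed — a plain periodogram can
  lock onto the saturation plateau instead.

## Desk-scale validation protocols

The reference experiments (hundreds of replicates, $10^4$ MCS, lattices
of $10^5$ sites) exceed what a test suite should run. The suite uses
scaled-down protocols that were validated once, before freezing, with
independent pilot runs:

* **Single-cell motility onset.** The onset of sustained migration near
  $\Delta\epsilon/\kappa_P \approx 500$ requires the reference cell size
  ($\epsilon_0 = 225$, equilibrium area $\approx 620$ sites, $R = 5$).
  Shrinking cells to $\epsilon_0 = 60$ — with $R = 5$ or a
  proportionally reduced $R = 2$ — destroys the threshold: pilot sweeps
  showed sustained migration already at
  $\Delta\epsilon/\kappa_P = 250$, because for small cells the
  polarization feedback loop is fluctuation-dominated. The suite
  therefore scales down *duration and replicate count*, not cell size,
  for this observable. A grid point is classified motile when the median
  over replicates of the second-half center-of-mass displacement exceeds
  five cell diameters.
* **Cluster rotation.** Four cells on a circular micropattern rotate
  persistently above an onset in $\Delta\epsilon/\kappa_P$. This
  phenomenon *does* survive desk scaling ($\epsilon_0 = 60$, $R = 3$,
  pattern radius $15.8$), provided the cluster is seeded on a concentric
  sub-disk with a free annulus: seeding the cluster as a full
  tessellation of the disk jams it (every elementary move then fights
  the confinement energy, and the cluster freezes into a drift-and-jam
  state). Rotating runs are classified by the net rotated angle, and
  their unidirectionality is measured as
  $|\sum \omega| / \sum |\omega|$.
* **Growth bursts.** A confluent strip of cycling cells released from
  its walls shows synchronized division waves; the mean-density series
  rises in bursts spaced $T_g + T_d$. The period is read with
  `burst_period()` (see above) on a lattice wide enough that the front
  never reaches the boundary within the recorded window.
* **PRW statistics.** Early-lag MSD slopes need lags
  $\tau < \tau_p / 3$; the diffusive slope 1 is only approached slowly
  (the Fürth log-log slope is still $\approx 1.25$ at
  $\tau = 5\tau_p$), so the late fit uses $\tau \in [7\tau_p, 15\tau_p]$
  and run lengths of at least $40 \tau_p$.

## Known limitations

* The degeneracy under $(\Delta\epsilon, \kappa_P) \to (2\Delta\epsilon,
  2\kappa_P)$ is statistical, not exact: the thermal energy scale and
  $\kappa_A$ are *not* rescaled, so observables agree within confidence
  intervals at moderate replicate counts rather than point-wise.
* At paper scale the confined-cluster experiment can enter long jammed
  transients; the desk-scale protocol above avoids them, but individual
  replicates near the rotation onset may still stall.
* `dominant_period()` (periodogram) is provided for general use but is
  not robust for burst-period extraction once the tissue saturates; use
  `burst_period()` for that observable.

## A short run

```{r, eval = FALSE}
library(polcpm)
p <- cpm_params(kappa_A = 0.18, kappa_P = 0.06, eps0 = 60,
                delta_eps = 39, R = 5, mu = 0.1)
out <- simulate_single_cell(p, t_sim = 3000, record_every = 10, seed = 1)
fit <- fit_prw(msd(out$positions, dt = 10))
c(v = fit$v, tau_p = fit$tau_p)
```
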