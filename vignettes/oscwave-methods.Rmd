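---
title: "Traveling waves in forced oscillator chains: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling waves in forced oscillator chains: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscwave)
```

## The model

`oscwave` studies a semi-infinite chain of identical phase oscillators
with strictly feed-forward (synfire-chain-like) coupling. Each site $s$
carries a phase $\theta_s$ on the circle $\mathbb{T} = \mathbb{R}/\mathbb{Z}$,
advancing at base speed 1 (time is rescaled so the natural frequency is 1).
The interaction is the square-pulse caricature of a type-I oscillator:
site $s$ accelerates to speed $1+\epsilon$ exactly while its upstream
neighbour's phase lies in the *stimulus window* $[0, a_0]$ (mod 1) **and**
its own phase lies in the *response window* $[0, a_1]$ (mod 1):

$$
\dot\theta_s \;=\;
\begin{cases}
1+\epsilon & \text{if } \theta_{s-1} \bmod 1 \le a_0
             \text{ and } \theta_s \bmod 1 \le a_1,\\
1 & \text{otherwise,}
\end{cases}
\qquad s \ge 1,
$$

with site 0 replaced by a periodic forcing signal $f$: a continuous
increasing lift with slope at least 1, $f(0)=0$ and
$f(t+\tau) = f(t)+1$. Phases are stored as **lifts** (unbounded reals,
reduced mod 1 only for display and for the window conditions); this makes
the integer-translate bookkeeping of the return-map analysis exact.

Because the coupling is strictly unidirectional, truncating the chain at
$S$ sites is exact, and the whole solution is obtained by solving one
forced scalar equation per site, inductively downstream.

### Parameters

| parameter | meaning | units | constraint |
|---|---|---|---|
| $\epsilon$ | coupling (acceleration) strength | dimensionless | $>0$ |
| $a_0$ | stimulus window width | circle units | $(0,1)$ |
| $a_1$ | response (PRC) window width | circle units | $(0,1)$ |
| $\tau$ | forcing period | time | $0<\tau\le 1$ for the uniform ramp |
| $\alpha$ | per-site phase shift of a wave | time | inside the admissibility interval |

Both windows are the **closed** intervals $[0,a_0]$ and $[0,a_1]$; the
boundary choice is immaterial (it affects the trajectory on a measure-zero
set of instants — see "Numerical choices").

## Exact event-driven integration

Trajectories are continuous, strictly increasing and piecewise affine with
slopes in $\{1, 1+\epsilon\}$, so the flow can be integrated exactly:
between events the slope is constant and the next event is the earliest of

1. the oscillator reaching the response-window edge $a_1$ (mod 1),
2. the oscillator reaching the next integer (firing),
3. the upstream signal crossing $a_0$ (mod 1),
4. the upstream signal crossing the next integer.

All four times are closed-form intersections of affine pieces — no
root-finding, no step-size error. The only tolerance is an
event-*merging* threshold (default $10^{-12}$): events closer than this
are processed in one pass, and pieces of zero length (boundary grazing,
simultaneous events) are pruned from the output. An independent
explicit-stepping oracle (`euler_oracle`) provides an $O(dt)$ cross-check
of the engine; the test suite verifies first-order convergence on random
fixtures.

## The closed-form traveling wave

A traveling wave (TW) is a solution $\theta_s(t) = f(t+\alpha s)$: the
forcing shape repeats at every site, delayed by $\alpha$; $\alpha/\tau$ is
the wave number. For the stable family the shape is the three-piece
profile

$$
\Theta_{\alpha,\sigma}(t) =
\begin{cases}
t & t \le \alpha,\\
\alpha + (1+\epsilon)(t-\alpha) & \alpha \le t \le \sigma + \alpha,\\
\epsilon\sigma + t & t \ge \sigma+\alpha,
\end{cases}
$$

with fast-piece length $\sigma = \min\{t_0, t_1\}$, where
$t_0 = \min\{a_0, (a_0+\alpha\epsilon)/(1+\epsilon)\}$ is when the
upstream leaves its window and $t_1 = (a_1-\alpha)/(1+\epsilon)$ is when
the site leaves its own, and period $\tau = 1-\epsilon\sigma$. With
`rational()` parameters all of these are exact fractions.
`build_tw()` verifies every constructed shape by simulation: one site
forced with the shape and started on the wave must reproduce the shape
shifted by $\alpha$ to $10^{-9}$; this is the defining identity of the
wave and guards the closed forms against regressions.

### Admissibility intervals

Three nested intervals of $\alpha$ (reported by `alpha_intervals()`, with
their images under $\alpha \mapsto \tau(\alpha)$):

* **existence** — a case-(a) wave exists iff $0 \le \alpha < a_1$ and
  $f(\tau-\alpha) \ge a_0$, i.e. the upstream shape has cleared the
  stimulus window by the time the site fires. Resolving
  $f = \Theta_{\alpha,\sigma}$ branch by branch gives
  $\alpha \le \max\{(1+\epsilon)(1-a_0)-\epsilon a_1,\,
  (1-a_0+\epsilon(1-a_1))/(1+\epsilon)\}$ when $a_0 < a_1$, but
  $\alpha \le 1-a_0$ when $a_0 \ge a_1$: in the wide-stimulus-window
  regime the shape reaches $a_0$ on its slow tail, where
  $f(\tau-\alpha) = 1-\alpha$, and the familiar $\max\{\cdot\}$ form
  overstates the bound. The package implements the branch-resolved
  condition; the test suite falsifies the $\max\{\cdot\}$ form directly
  by simulating the would-be shape just above $1-a_0$ and watching the
  wave identity fail.
* **stable** — the wave's stroboscopic fixed point is attracting iff the
  site leaves its response window before the upstream leaves the stimulus
  window, $t_1 < t_0$, i.e. $\alpha > \alpha_0 =
  \max\{a_1-(1+\epsilon)a_0, (a_1-a_0)/(1+\epsilon)\}$. This interval is
  non-empty for *every* valid parameter set (a property test checks 1000
  random draws).
* **uniform** — the sub-range on which the uniform ramp $g(t)=t/\tau$
  also generates the wave:
  $(a_1-a_0-\epsilon a_0(1-a_1))/(1+\epsilon a_0) < \alpha <
  (1-a_0)(1+\epsilon(1-a_1))/(1+\epsilon a_0)$, intersected with the
  stable interval. It can be empty for strong coupling.

Interval endpoints follow the strict/non-strict pattern of the defining
inequalities: existence is closed at 0 and at the clearing bound, open at
$a_1$; stable is open at $\alpha_0$. The degenerate shift $\alpha = 0$
(wave number 0) is excluded from `build_tw()` by default because a wave
proper needs $\alpha \in (0,\tau)$; a flag re-admits it for testing. The
map $\alpha \mapsto \tau(\alpha)$ is continuous and piecewise affine but
not injective (decreasing while $\sigma = t_0$, increasing once
$\sigma = t_1$), so `alpha_of_tau()` returns *all* preimages rather than
imposing a canonical inverse.

## The stroboscopic map

The period return map $F_f(\vartheta) = \theta_1(\vartheta,\tau) - 1$ is
the lift of an orientation-preserving circle homeomorphism and is exactly
piecewise affine, each slope an integer power of $1+\epsilon$.
`strobe_decompose()` recovers the decomposition by scanning initial
phases, grouping them by the *event signature* of the one-period
trajectory (the ordered list of event kinds): the map is affine exactly
while the signature is constant, so breakpoints are located by bisection
on the signature and then sharpened to the intersection of the two
adjacent affine branches, leaving no bisection residual. A complexity cap
(default 64 pieces) guards against pathological non-wave forcings.

For a stable-case wave forcing the decomposition has exactly four pieces —
two rigid rotations interspersed by one contraction (slope
$(1+\epsilon)^{-1}$, containing the wave point $f(\alpha)$) and one
expansion (slope $1+\epsilon$, containing the unique unstable point
$\vartheta_{\mathrm{unst}}$). Consequences, each verified by the tests:

* every orbit off $\vartheta_{\mathrm{unst}}$ converges to $f(\alpha)$
  mod 1, with eventual per-period contraction $(1+\epsilon)^{-1}$;
* the rotation number vanishes (estimated with a tail average, which is
  exact both for maps with an attracting fixed point and for rigid
  rotations);
* slope-1 pieces through a fixed point are reported as *neutral
  segments*, not points.

Downstream sites follow a non-autonomous composition of return maps
driven by the upstream trajectory. `composed_site_map()` computes it by
direct chain simulation sampled at period multiples (trading memory for
exactness rather than storing per-period map objects). Each site has
exactly one exceptional initial phase; `find_unstable_initial()` locates
it by bisection on the integer translate of the orbit limit, which jumps
by one revolution across the exceptional point. Near the exceptional
phase the escape time grows only logarithmically (rate $\log(1+\epsilon)$
per period), so 150 periods per orbit evaluation resolves the location to
$10^{-10}$ comfortably.

For site 2 with site 1 on the wave, the exceptional phase is the unstable
fixed point of the $\alpha$-shifted return map — the unstable *periodic
solution* evaluated at $t=\alpha$. It is not, in general, a time shift of
the wave shape $f$ itself evaluated at $t_{\mathrm{unst}}+\alpha$: the
shifted shape fails the forced equation on part of the period (the
package's worked example gives $0.3$, not $f(t_{\mathrm{unst}}+\alpha) =
7/30$, and three independent routes in the test suite agree).

## Wave generation experiments

`run_generation_experiment()` starts a truncated chain from i.i.d.
uniform random phases and drives it with (i) the wave shape itself,
(ii) the uniform ramp of the same period, or (iii) a seeded admissible
perturbation of the shape. In all three cases the attractor is the
*constructed wave shape* — under the ramp the chain converges to $f$, not
to the ramp — provided $g(0)=0$ and $g(\sigma) < a_0 < g(\tau-\alpha)$
(`check_forcing_admissible()` reports each condition's margin).
Convergence is measured by the stroboscopic circle distances
$d_s(n) = d(\theta_s(n\tau), f(n\tau+\alpha s))$.

Choices made here:

* **Verdict**: trailing window of 20 periods, tolerance $10^{-6}$,
  default horizon 500 periods; all configurable. The transient has two
  parts: a drift through the rigid-rotation pieces at
  $\epsilon\,(t_0-\sigma)$ per period, then geometric contraction at
  $(1+\epsilon)^{-1}$. For weak coupling with a narrow stimulus window
  the drift dominates and can exceed 500 periods per site; the
  acceptance tests therefore run weakly coupled fixtures to 1500
  periods.
* **First-crossing index**: the first period from which $d_s$ *stays*
  below $10^{-4}$ (a transient dip does not count). With this definition
  the downstream ordering — site $s$ converges only after site $s-1$ —
  holds on every converged run in the suite.
* **Perturbed forcings** are built by jittering the interior knots of the
  shape under the monotonicity/slope/admissibility constraints, halving
  the jitter until valid, rather than by characterising the full
  neighbourhood of admissible signals.
* **Exceptional initials** are a measure-zero set and are ignored for
  random runs; they are exercised by targeted runs started exactly on
  them.

## The synthetic fixture generator

`sample_admissible_fixture()` draws $\epsilon \sim U[0.05, 1]$ and
$a_0, a_1 \sim U[0.05, 0.95]$ — covering weak to strong coupling and
narrow to wide windows while staying away from the degenerate edges 0 and
1 — then draws $\alpha$ uniformly in the requested interval (existence,
stable, or uniform), redrawing the parameters when the requested interval
is empty. Random initial configurations are i.i.d. uniform on $[0,1)$.
This emulates the study conditions of the analysis: arbitrary initial
phases, admissible parameters, periodic forcing. It does **not** emulate
features of biological oscillator networks — heterogeneous units, noise,
conduction delays, smooth response curves, bidirectional coupling — so
passing tests demonstrate the piecewise-affine theory faithfully, not
robustness of real synfire chains.

## Numerical choices and degenerate inputs

* Tolerances: event merging $10^{-12}$; validation $10^{-9}$; both
  configurable per call.
* Window boundaries are closed; an event landing exactly on a boundary
  produces a zero-length fast piece which is pruned, so the convention
  cannot change the trajectory. Simultaneous self/upstream events are
  processed in one pass; the order is immaterial by construction.
* A forcing with slope exactly 1 everywhere (the identity ramp at
  $\tau=1$) is valid; slopes below 1 anywhere are rejected because the
  event inversion and the theory both require increasing signals with
  slope at least 1. Since valid forcings are strictly increasing, they
  cannot dwell on the window edge, so no grazing ambiguity arises.
* The boundary tie $t_0 = t_1$ ($\alpha = \alpha_0$) is classified
  neutral with a warning rather than silently assigned to either side.
* Exact-rational mode covers the closed-form layer (wave times, shape
  knots); the event-driven engine itself runs in double precision, whose
  error over the test horizons stays below $10^{-12}$.

## Problem sizes

The test and acceptance workloads use desk-scale sizes chosen to make
every property decisive yet quick: chains of 5–20 sites, horizons of
10–1500 periods, 1000-draw parameter sweeps, a $dt = 10^{-5}$ oracle over
5 periods, and 200-orbit basin scans. Each quantity's convergence rate is
known (geometric contraction, $O(dt)$, $O(1/n)$), so these sizes leave
orders of magnitude of margin at the stated tolerances.

## Known limitations

* Only the forced semi-infinite (truncated) chain is implemented — no
  ring topology, no bidirectional coupling, no noise.
* Closed-form construction covers the stable case (a) family only; the
  other wave cases (b), (c), (c′) are classified but not constructed.
* The maximal neighbourhood of admissible forcings is not characterised;
  membership is checked signal by signal.
* No continuation toward smooth response curves; all results are for the
  square-window caricature.
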