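---
title: "The Epileptor neural field: model, numerics, and termination analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Epileptor neural field: model, numerics, and termination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`epifield` implements a neural field extension of the Epileptor, a
phenomenological model of focal seizure dynamics with three interacting time
scales: a fast population $(u_1, u_2)$ producing the low-voltage fast
activity (LVFA) seen at seizure onset, a spike-and-wave population
$(q_1, q_2)$ producing the 2–3 per second large-amplitude discharges (SWDs)
seen as the seizure unfolds, and a slow *permittivity* variable $v$ standing
in for slowly varying quantities (extracellular ion concentrations,
metabolism, tissue oxygenation) that carry a site into and out of the
seizure.  On a periodic one-dimensional domain of length $L = 6\pi$ the
state evolves as

$$
\begin{aligned}
\partial_t u_1 &= u_2 - f_1(u_1, q_1, v) - v + I_1
  + \gamma_{11}\, w_1 * S(u_1, \theta_{11}) + \textstyle\sum_j
  \gamma_{het,j}\, w_{het}\, S(u_{1,j}, \theta_{het}) \\
\partial_t u_2 &= 1 - 5u_1^2 - u_2 \\
\partial_t v   &= \tfrac{1}{\tau_0}\!\left(4(u_1 - u_0(x)) - v\right) \\
\partial_t q_1 &= -q_2 + q_1 - q_1^3 + I_2 + 2 q_3 - 0.3 (v - 3.5)
  + \gamma_{22}\, w_2 * S(q_1, \theta_{22}) \\
\partial_t q_2 &= \tfrac{1}{\tau_2}\!\left(-q_2 + f_2(q_1)\right) \\
\partial_t q_3 &= -\tfrac{q_3}{\tau_{12}}
  + 0.001\!\left(a_{12} u_1 + \gamma_{12}\, w_{12} * S(u_1, \theta_{12})\right)
\end{aligned}
$$

with the Heaviside firing rate $S(u, \theta) = H(u - \theta)$ (we adopt
$H(0) = 1$: upper semicontinuity; threshold hits have measure zero along
trajectories), the piecewise nonlinearities $f_1, f_2$ of the original
Epileptor, the Laplacian local kernel $w(x) = e^{-|x|}/2$ shared by the
three homogeneous couplings, and a Gaussian long-range kernel
$w_{het}(x) = e^{-x^2/8}/\sqrt{8\pi}$ between fields.  The auxiliary
variable $q_3$ is the exact ODE recast of the exponential-memory drive
$0.002\,g(u_1)$ of the mass model; it is initialised at its equilibrium
value, never at zero, so the interictal state is an exact fixed point.
The diagnostic $K = 2q_3 - 0.3(v - 3.5)$ lumps the slow drive on the
spike-wave population into one number per site; it controls whether that
population oscillates (SNIC bifurcation at
$K_c = 2/(3\sqrt{3}) - I_2 \approx -0.065$) and its spatial maximum predicts
where the next discharge starts.

All quantities are in the model's arbitrary units; no conversion to
millimetres or seconds is applied anywhere.

### Heterogeneous coupling

The long-range term is stated in the field equations as a product of a
kernel and a firing rate, which leaves its exact action open.  We use a
symmetric two-point form: the source field's firing rate is sampled with a
Gaussian weight around the source centre,
$A_j = \int w_{het}(y - x_s)\, S(u_{1,j}(y), \theta_{het})\, dy$, and
injected into the target with a Gaussian profile around the target centre,
$\gamma_{het}\, A_j\, w_{het}(x - x_t)$.  This keeps the coupling symmetric
in its treatment of the two fields and reduces to a point-to-point
connection in the narrow-kernel limit.

### Excitability and the critical value

A site is epileptogenic when its excitability $u_0$ exceeds the knee of the
interictal branch.  The equilibrium solves $h(u_1) = 4(u_1 - u_0)$ with
$h(u_1) = -u_1^3 - 2u_1^2 + 4.1$, and loses stability through a saddle-node
when the root reaches the local minimum of $h$ at $u_1 = -4/3$:

$$u_{0c} = -\tfrac{4}{3} - h(-\tfrac{4}{3})/4 = -2.0620\ldots$$

`epileptogenic_threshold()` returns this value and
`autonomy_threshold_bisect()` reproduces it dynamically by bisection on
long simulations.  The published account states the boundary once as
$u_0 > -2.1$ and once as $u_0 > -2.91$; the knee analysis and the
simulated bisection both support $\approx -2.06$, consistent with the
first figure, and we treat the second as a misprint (it is close to
nothing the nullcline geometry produces).

The default field is uniformly epileptogenic at $u_0 = -1.8$.  A tapered
profile (`u0_profile_epileptogenic()`) with low-excitability guards near
the domain ends is also provided, but it is not the default: sites inside
the taper carry a faster permittivity drift once recruited and terminate
several hundred time units before the interior, which masks the
termination-synchrony phenomena the package is designed to expose.  On a
periodic domain a guard ring is unnecessary in any case.

## Numerics

The integrator (compiled, RK4 with fixed step) evaluates the periodic
convolutions of the Laplacian kernel by an exact $O(N)$ pair of recursive
geometric sweeps — the discrete counterpart of the kernel's exponential
decay — normalised to preserve constants; this equals the FFT evaluation of
the periodised, mass-normalised kernel to machine precision (tested), at a
fraction of the cost.  An R-level `field_rhs()` is the reference
implementation; the compiled step is cross-checked against it to $10^{-12}$.

Defaults: $N = 256$ grid points over $L = 6\pi$ ($\Delta x \approx 0.074$,
about 14 points per kernel decay length), $\Delta t = 0.025$.  Both are
exposed and covered by step-halving and grid-doubling tests.  White
Gaussian noise of variance $\sigma^2 = 0.001$ (when enabled) is added to
$q_1, q_2$ after each deterministic step with standard deviation
$\sigma\sqrt{\Delta t}$ (Euler–Maruyama convention; RK4 has no consistent
strong treatment of white noise, and the noise here shapes correlation
distributions rather than trajectories).

### Initial condition and stimulation

Every site starts at the interictal equilibrium of its local excitability.
Epileptogenic sites have no equilibrium; they are seated on the interictal
branch at the equilibrium of a fixed sub-threshold reference excitability
$u_{0c} - 0.6$ (permittivity $v_0 \approx 3.45$).  This choice makes the
standard stimulation protocol work as intended: by $t = 400$ the
permittivity has drifted to $\approx 3.05$, where the strength-1,
width-1.57, 10-time-unit boxcar pulse added to $I_1$ removes the interictal
fold locally and ignites a travelling front, while the autonomous
transition of unstimulated tissue waits until $t \approx 1000$.  The
`init_margin` argument moves this reference; smaller margins shorten the
autonomous latency (used for the slow-recruitment regime, where offsets
propagate).

## Wavefront speed: shooting in the co-moving frame

With the permittivity frozen at $\bar V$, the recruiting front is a
travelling wave $U_1(\xi)$, $\xi = x + c_1 t$.  Using the kernel identity
$\gamma_{11} S = (1 - \partial_{xx})(\partial_t u_1 + u_1^3 - 3u_1^2 - u_2
- I_1 + v)$, the profile satisfies a 5th-order system (3rd order in $U_1$,
2nd in $U_2$) — or a 3-variable system for the averaged (no fast
oscillation) reduction.  The front is the heteroclinic orbit from the
interictal fixed point to the ictal attractor (a limit cycle of the
clamped fast subsystem, or the upper state for the reduced variant).

`shoot_front_speed()` launches the frame trajectory from the fixed point
along its one-dimensional unstable eigendirection (the $e^{+\xi}$ kernel
mode) with a $10^{-6}$ perturbation, integrates with an Euler scheme whose
step scales with the speed ($h = 2\times10^{-4} c_1$), and classifies the
direction in which $U_1$ ultimately escapes.  Trajectories near the
connection are captured by the ictal attractor and wind around it many
times before escaping; the integration is always continued until escape,
because the terminal direction of a truncated, still-captured trajectory
carries no information.  The speed is bracketed by the escape-direction
dichotomy over a log-spaced scan and refined by bisection to a relative
$2\times10^{-3}$; the distance of the terminal segment to the attractor
polyline is reported as the objective.  A distance-minimising optimiser
over the speed was tried first and abandoned: the distance is nearly flat
across the capture window and its minimum is a poor estimator.

Agreement with direct frozen-permittivity field simulations is 1–8% around
$\bar V = 3.0$–$3.1$ (tested).  Two known limitations: (i) for very slow
fronts close to the fold of the interictal branch (e.g. $\bar V = 3.2$,
$c_1 \approx 0.011$) the strict travelling-wave speed exceeds the
PDE-selected front speed by $\sim$25% — the wave train shed behind the
front destabilises the steady profile there; (ii) agreement also degrades
when $\theta_{11}$ approaches the rest state, where the Heaviside switches
on the oscillatory tail of the front.  Both regimes still give the right
order of magnitude.

The averaged reduction removes the fast oscillation that intermittently
silences the Heaviside coupling on the front, so its front is roughly an
order of magnitude faster (ratio $\approx 12$ at $\bar V = 3$); this is the
mechanistic statement that LVFA slows seizure spread.

## Discharge speed: chain of relaxation oscillators

Within the recruited territory the spike-wave population behaves as a chain
of oscillators parameterised by $K$.  On the left branch of the cubic
nullcline ($q_1 < -1/\sqrt3$, $f_2 = 0$, trajectory glued to the
nullcline), the time to reach the knee from phase $q_1^i$ is the explicit
quadrature

$$T(q_1^i) = \int_{q_1^i}^{-1/\sqrt3}
  \frac{\tau_2 (1 - 3q_1^2)}{-q_1 + q_1^3 - I_2 - K}\, dq_1,$$

and the apparent propagation speed between neighbouring sites is
$c_2 = \Delta x / (T(q_1^j) - T(q_1^i))$ (`swd_transit_time()`,
`swd_speed()`; adaptive quadrature, knee fixed analytically, singular
denominators rejected explicitly).  Coupling $\gamma_{22}$ is neglected in
the quadrature; simulation confirms it changes sweep speeds by well under a
factor of two.

`swd_speed_ratio()` evaluates the quadrature at $K = 1.5$ on neighbour
phase pairs pooled from snapshots spanning the discharge-active phase of a
simulated seizure.  Mid-sweep snapshots carry staggered phases whose
apparent speed matches the sweep itself (a few a.u. per time unit); between
discharges and towards termination the phases are nearly synchronous and
the apparent speed is orders of magnitude higher.  The pooled median is
$\sim 300\times$ the wavefront speed under default conditions — the
two-orders-of-magnitude separation between discharge propagation and
recruitment, and the reason a single late discharge can terminate the whole
field near-simultaneously through the homoclinic offset bifurcation.

## Termination analysis

The analysis path mirrors what one would do with intracranial recordings:
band-pass (1–10 Hz, fifth-order forward-backward Butterworth for real
data), per-channel onset/offset detection, pairwise termination delays and
pre-offset correlations, flat-kernel mean-shift clustering of the delays,
and connectivity features per contact pair.

* Onset/offset on simulated fields threshold $u_1$ at 0 with a 5-time-unit
  debounce; suprathreshold runs separated by less than 30 time units (a few
  discharge cycles) merge, so trailing discharges count towards the offset.
  When a recording contains recurrent seizures the first episode is
  analysed.
* The pre-offset window for simulated signals is 50 time units (several
  discharge cycles) ending at the earlier offset of the pair; real
  recordings use the 2-s window dialect.  Same-electrode pairs are excluded
  when electrode labels exist.
* Mean-shift uses a flat kernel with Silverman's rule as the default
  bandwidth, merges modes within one bandwidth (strongest support first)
  and labels points by nearest surviving mode; it reproduces the reference
  scikit-learn implementation label-for-label on separated clusters.
* Discharge cataloguing takes local maxima of $q_1$ above 0, sharpened by
  parabolic interpolation below the recording stride (the sweep crosses the
  field in a few time units, so sub-stride timing matters for source
  localisation), groups them into events by temporal adjacency (gap 5),
  and classifies the source trajectory as stationary when its span stays
  below 10% of the recruited extent.  The K-argmax source prediction is
  evaluated against detected sources with the same 10%-of-extent
  tolerance.
* Mann–Whitney U uses exact enumeration (ties handled exactly) up to a
  combined $n = 12$ and the tie-corrected normal approximation with
  continuity correction beyond.

The synthetic generators close the loop without patient data: surrogate
multichannel recordings with cluster-structured offsets and a tunable
shared component (what real SEEG adds that these do not: 1/f background,
artefacts, non-stationary spectra, volume conduction), and block-structured
region connectomes with electrode/contact tables.  Passing tests on these
fixtures demonstrates the pipeline's correctness and the model's internal
consistency, not clinical validity.

## Problem sizes used by the test-suite

Deterministic single-field demonstrations run at the default $N = 256$ for
2500 time units; multi-seed, two-field experiments use $N = 128$ over 2800
time units (the kernel is still resolved by 7 points per decay length and
the front speed changes by under 5% between the two grids), with the
second field at $u_{0,2} = -2.0$ — excitable but slower to transition, as
in the staged-recruitment regime.  Shooting-versus-simulation consistency
is verified at $(\bar V, \gamma_{11}) \in \{(3.0, 1), (3.0, 1.5),
(3.1, 1)\}$.

## Known limitations

One spatial dimension only; no conduction delays (they alter pattern
stability, not the patterns, on these scales); Heaviside rates only (no
sigmoid variant); the shooting method's slow-front limitation above; the
termination-delay clustering is one-dimensional by design.  The package
consumes precomputed region adjacency and streamline-count matrices and
performs no imaging or tractography itself.
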