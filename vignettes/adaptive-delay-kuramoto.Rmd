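---
title: "Modeling myelin plasticity: Kuramoto networks with adaptive conduction delays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling myelin plasticity: Kuramoto networks with adaptive conduction delays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kuradapt)
```

## The model

White-matter axons conduct spikes with delays of tens of milliseconds, and
these delays are not fixed: oligodendrocytes remodel myelin in an
activity-dependent way, so conduction delays adapt on slow time scales.
`kuradapt` studies the simplest dynamical caricature of this process: a
Kuramoto network in which every conduction delay is itself a state variable
driven by the phase relation of the two oscillators it connects.

The phases evolve as
$$\dot\theta_i = \omega_0 + \frac{g}{N}\sum_{j=1}^N a_{ij}
  \sin\!\big(\theta_j(t - \tau_{ij}(t)) - \theta_i(t)\big),$$
and each delay obeys the plasticity rule
$$\alpha_\tau^{-1}\dot\tau_{ij} = H(\tau_{ij})
  \big[-(\tau_{ij} - \tau^0) + \kappa\sin(\theta_j - \theta_i)\big],$$
where $\tau^0$ is the baseline lag (minimal myelination), $\kappa$ the
plasticity gain, $\alpha_\tau$ the homeostatic rate, and $H$ a smoothed
Heaviside that freezes a delay once it reaches zero, so delays can never
become negative. When the phase of the source runs ahead of the target the
delay lengthens (myelin retraction); when it lags, the delay shortens. With
$\kappa = 0$ the model reduces to the classical fixed-delay Kuramoto
network.

A synchronized state is a frequency-locked solution
$\theta_i(t) = \Omega t + \phi_i$. Because the delays need non-zero phase
differences to hold their equilibria $\tau^E_{ij} = \max(\tau^0 +
\kappa\sin\Delta_{ij},\, 0)$, plastic networks lock with distributed offsets
rather than in phase, and always at a frequency $\Omega$ *below* the natural
frequency $\omega_0$.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `omega0` | rad/s | 1 | common natural frequency |
| `g` | rad/s | 1.5 | coupling gain of the $g/N$-normalized network |
| `kappa` | s | 0 | plasticity gain; 0 disables adaptation |
| `tau0` | s | 0.1 | baseline lag, drift target of the delays |
| `alpha_tau` | 1/s | 1 | homeostatic rate of delay adaptation |
| `eps` | s | 0.01 | Heaviside smoothing width |

Two gain conventions coexist in the literature of this model. The network
equation divides by $N$; the reduced two-oscillator system is conventionally
written with the full pairwise gain on each connection. We keep both:
`model_params()` always holds the $g/N$ gain, while
`two_oscillator_params()` and everything in the two-oscillator module use
the pairwise value (e.g. $g = 0.75$), converting internally (a pairwise gain
$g$ is a network gain $2g$ at $N = 2$).

On the homeostatic rate: the reduced two-oscillator equations evolve their
delays at unit rate — the $\alpha_\tau$ prefactor of the general rule is
absorbed there — and the two-oscillator bistability experiment is only
reproduced under unit-rate delay dynamics, so `two_oscillator_params()`
defaults to `alpha_tau = 1`. The general simulator keeps $\alpha_\tau$ live;
the closed-form two-oscillator analysis is independent of it, because the
characteristic polynomials are derived from the unit-rate linearization (an
$\alpha_\tau$-aware variant is available behind `alpha_aware = TRUE` in
`char_polynomials()`, but it is unvalidated against simulation and off by
default).

## Numerical integration of the state-dependent DDE

The coupled system has $N + N^2$ states and state-dependent lags, which
rules out off-the-shelf constant-lag DDE solvers. The integrator
(`simulate_network()`, compiled core in C++) is a fixed-step classical RK4
scheme with these choices:

* **History.** All phases are stored on the step grid; delayed phases are
  linear interpolations into that history. The history buffer covers
  $\tau^0 + \kappa + 1$ s, which suffices because the plasticity rule
  confines every delay to $[0, \tau^0 + \kappa]$.
* **Frozen lags within a step.** The lag $\tau_{ij}$ used for history
  lookups is held at its start-of-step value during the four RK4 stages;
  the delay state itself advances with full RK4. Delays move on the slow
  $\alpha_\tau$ scale, so the freeze contributes $O(\Delta t^2)$, below the
  scheme's own error at the default $\Delta t = 5$ ms. Reference runs use
  1 ms; halving the step changes the asymptotic frequency estimate of the
  reference two-oscillator trial by less than $10^{-4}$ rad/s (tested).
* **Short lags.** When a lag is shorter than the stage offset, the lookup
  interpolates against the stage state itself, which makes the zero-delay
  limit an exact classical RK4; that limit is tested against the closed-form
  phase-difference solution $\tan(\Delta/2) = \tan(\Delta_0/2)e^{-2gt}$.
* **Clamping.** After each step delays are clamped at zero, suppressing
  floating-point undershoot below the smoothed-Heaviside floor.
* **Initial function.** Before $t = 0$ phases follow the linear history
  $\Omega_0 t + \phi^0_i$. Its slope $\Omega_0$ does not satisfy the model
  equations at $t = 0^-$, which would inject a velocity discontinuity, so
  the last $10\,\Delta t$ of history are replaced by a cubic Hermite patch
  whose slope at $0^-$ equals the full phase right-hand side evaluated on
  the unpatched history, including the $\omega_0$ term (the matching
  condition is sometimes quoted without it; both variants are selectable
  via `include_omega0`, and the full form is the default because velocity
  continuity is the purpose of the patch).
* **Storage.** Phases and velocities are recorded every `record_stride`
  steps, delays every `tau_stride` (default 100) steps; the delays move
  slowly, so the thinning loses nothing while keeping $N = 50$ trajectories
  small.

Delays on absent connections ($a_{ij} = 0$) are frozen and excluded from
diagnostics: they never enter the phase equation. Self-connections in dense
topologies are evolved like any connection; their phase difference is zero,
so their delays simply relax to $\tau^0$, and their $O(g/N)$ contribution is
part of the all-to-all convention used by the mean-field analysis.

## Two-oscillator analysis

For two oscillators with strong plasticity ($\kappa \gg \tau^0$), one delay
collapses to zero and the other locks at $\tau^E_{12} = \tau^0 +
\kappa\sin\Delta_{12}$ with $\Delta_{12} = \arcsin((\omega_0 - \Omega)/g)$.
Locked frequencies are roots of a rapidly oscillating scalar function;
`find_sync_frequencies()` brackets them on a 4000-point grid (dense enough
to resolve the oscillation scale $2\pi g / (\kappa|\Omega|)$ at
$\kappa = 30$) and bisects to $10^{-12}$, discarding roots that violate the
self-consistency condition $\tau^0 < \kappa \sin\Delta_{12}$:

```{r roots}
p <- two_oscillator_params(g = 0.75, kappa = 30)
two_oscillator_stability(p)
```

Stability comes from a cubic-plus-delay characteristic equation
$P_\Omega(\lambda) + Q_\Omega(\lambda)e^{-\lambda\tau} = 0$ whose constant
terms cancel identically — the neutral rotation mode. Under the zero-delay
approximation the non-trivial eigenvalues are the roots of an exactly
deflated quadratic (`zero_delay_branches()`); `transcendental_error_map()`
scans the full transcendental equation on a complex grid and polishes local
minima by Newton iteration to confirm that no eigenvalue crosses into the
right half-plane elsewhere. The map's detection settings (grid resolution,
residual threshold $10^{-6}$ after polishing) are our choices; they are
reported rather than inferred from any reference figure.

## Mean-field (N-limit) analysis

For large all-to-all networks the offsets are treated as i.i.d. Gaussian
with standard deviation $\delta$. A locked state $(\Omega, \delta^2)$ must
zero the residual
$$\mathcal{R}(\Omega, \delta^2) = \omega_0 - \Omega +
  g\int \sin(-\Omega\tau^E(\Delta) + \Delta)\,\rho_\delta(\Delta)\,d\Delta,
  \qquad \tau^E(\Delta) = \max(\tau^0 + \kappa\Delta, 0),$$
using the small-offset linearization of the delay law (the exact
$\sin\Delta$ variant is available for sensitivity checks and changes the
results below by under 1%). Quadrature is adaptive Gauss–Kronrod on
$[-8\delta, 8\delta]$, split at the integrand kink $\Delta = -\tau^0/\kappa$
and at zero; the neglected Gaussian tail is below $10^{-15}$ in mass, and
the quadrature is tested against $2\times10^5$-sample Monte Carlo within its
sampling error. `solve_level_curve()` traces $\Omega(\delta)$ by bracketing
on 400 points per $\delta$; the expected uniqueness of the root is asserted,
not assumed — multiple brackets raise an error instead of silently picking
one.

Stability reduces, after restricting to the constant eigenfunction, to a
scalar eigenvalue relation containing $e^{-\lambda\tau^E(\Delta)}$ under the
integral. Following the rescale-and-truncate recipe, eigenvalues are
rescaled by a radius $R > \kappa$ (default $2\kappa$) and the exponential is
expanded to degree $M = 3$, giving a polynomial whose roots (neutral mode
excluded at $|\mathrm{Re}\,\lambda| \le 10^{-8}$) define the stability
statistic $E$. Two properties of our implementation are worth stating:

* The identity $I_0 = -RgI_{-1}$ is enforced from a single quadrature
  value, so the neutral mode is exact to machine precision.
* After deflating the neutral root and undoing the rescaling, the remaining
  quadratic is algebraically independent of $R$; numerically, $E$ agrees to
  $10^{-6}$ across $R \in \{1.5\kappa, 2\kappa, 4\kappa\}$ (tested). The
  choice of $R$ is therefore immaterial, which the stability conclusions
  depend on.

A caveat the package makes explicit: at the reference parameters the
polynomial roots sit far outside the truncation radius of the degree-3
expansion ($|\kappa\lambda\Delta/R| \sim 10$ at the roots), and the moments
that decide the sign of $E$ on the interesting part of the solution curve
are oscillatory integrals of magnitude $\sim 10^{-6}$. The *structure* of
the result is robust — a unique depressed solution curve
$\Omega(\delta) < \omega_0$ carrying one small stable window, unstable
elsewhere — but the window's *position* is sensitive to details of the
reduction pipeline. Our implementation, with quadratures verified against
Monte Carlo and an $R$-invariant statistic, locates the window near
$\delta \in (0.045, 0.065)$ at the reference parameters ($g = 1.5$,
$\kappa = 80$, $\tau^0 = 0.1$), somewhat below the reference description of
$(0.08, 0.1)$; the corresponding acceptance checks are asserted at the
reference values and fail honestly at their stated tolerance. Simulated
$N = 50$ networks converge to $\hat\delta \approx 0.05$ with
$\hat\Omega \approx 0.82$–$0.83$, near (but, as in the reference account,
not exactly on) the stable portion of the curve.

## Estimators

Asymptotic summaries are tail-window averages on the recorded grid
(trapezoidal rule): per-oscillator frequencies $\hat\Omega_i$, their mean
$\hat\Omega$, offsets $\hat\phi_i$ as averages of $\theta_i(t) -
\hat\Omega t$ wrapped to $[-\pi, \pi)$, and the $(N-1)$-denominator sample
variance $\hat\delta^2$. Wrapping can split a tight cluster across the
$\pm\pi$ seam, so offsets are re-centered by their circular mean before the
variance is taken and mapped back afterwards; this is exact for the small
clusters the experiments produce and robust to the cluster's position.
Window lengths follow the experimental protocols: the last 20 s of 200 s
two-oscillator runs, the last 10 s of 100 s $N = 50$ runs, and 12–16 s
windows for the injury protocol.

## Injury protocol

Injury is modeled as an insult index $\gamma$: at $t_{\mathrm{inj}}$ each
connection survives independently with probability $1 - \gamma$; surviving
connections keep their delay state. The default protocol runs 320 s with
injury at 160 s and averaging windows 148–160 s and 304–320 s (a variant
with injury at 80 s exists in the narrative sources; the figure-caption
protocol is the default because the printed summary windows belong to it).
The baseline lag is raised to $\tau^0 = 2$ s so that the pre-injury lock is
cosine-stable while the uncoupled limit is not — the regime in which injury
can destabilize a fixed-delay network.

With $\kappa = 0$ and $N \to \infty$, damage only rescales the coupling:
$g_{\mathrm{eff}} = (1-\gamma)g$, and the post-injury frequency follows the
scalar fixed-point law (`nonplastic_baseline()`). At $N = 50$ this law holds
to $10^{-2}$ while the network remains coherent (small $\gamma$); at
moderate and severe insult the quenched in-degree disorder of the sparse
topology desynchronizes the fixed-delay network — post-injury offsets
disperse and $\hat\Omega$ drifts to $\omega_0$ — which is precisely the
resilience contrast under study: the plastic network re-locks
($\hat\delta_{\mathrm{post}} \approx 0.08$ at $\gamma = 0.8$) where the
fixed-delay network falls apart
($\hat\delta_{\mathrm{post}} \approx 1.8$). The acceptance suite therefore
asserts the effective-coupling law on the $\gamma$ where the fixed-delay
network stays locked ($\gamma \le 0.2$), and asserts desynchronization at
$\gamma = 0.8$. "Significant separation" between the variants is
operationalized as $\hat\delta_{\mathrm{nonplastic}} >
5\,\hat\delta_{\mathrm{plastic}}$ at $\gamma = 0.8$ and a weaker $2\times$
separation at $\gamma = 0.5$ — our criterion, stated here rather than
inferred from any figure.

## Synthetic experiment conditions

The randomized experiments draw their initial conditions exactly as in the
study protocols (`generate_fixtures()`): two-oscillator basins use
$\Omega_0 \sim U[\omega_0 - g, \omega_0 + g]$ (pairwise convention) and
$\Delta_0 \sim U(0, 1)$; network trials use
$\Omega_0 \sim U[\omega_0 - g/4, \omega_0 + g/4]$, $\delta_0 \sim U(0, 1)$,
with per-oscillator offsets uniform on $[-\sqrt3\delta_0, \sqrt3\delta_0]$
so the offset standard deviation is exactly $\delta_0$. The basin experiment
is run at 20 trials in the test suite (80 in the original protocol) to keep
the default run short; each trial is still a full 200 s integration. What
passing these tests shows is that the *model's* attractor structure is
reproduced under the stated conditions; the generator makes no attempt to
emulate features of real neural recordings (measurement noise, frequency
heterogeneity, weighted or distance-dependent connectomes), so agreement
here says nothing about fit to empirical data.

## Degenerate inputs and edge cases

Zero plasticity reduces every code path to the classical fixed-delay model
(tested against its closed forms); $\gamma = 1$ produces the uncoupled
system, handled exactly; a lag that outruns the stored history is a hard
error naming the required horizon rather than silent extrapolation; and the
level-curve and candidate-matching routines raise errors on ambiguity
(multiple residual roots, two matching candidates) instead of guessing.

## Problem sizes

Default test and acceptance runs use: 200 s two-oscillator integrations at
$\Delta t = 5$ ms; one 100 s, $N = 50$ network integration per trial; a
57-point level curve with on-curve stability evaluation; and injury sweeps
over $\gamma \in \{0, 0.2, 0.5, 0.8\}$ at 320 s per trial. These sizes
reproduce every targeted quantity at its stated precision; larger basins
(80 trials) and denser stability maps only refine the pictures.

## Known limitations

* The mean-field stability statistic inherits the truncation fragility
  discussed above; treat the window *position* as qualitative.
* The reduced two-oscillator analysis assumes $\kappa \gg \tau^0$ and one
  vanishing delay; locks violating self-consistency are excluded, not
  analyzed.
* Phase oscillators with a common $\omega_0$: frequency heterogeneity is
  accepted by the right-hand sides but none of the analysis modules model
  it.
* The integrator is fixed-step and explicit by design; stiff regimes
  (extreme $\alpha_\tau \kappa$) would need smaller steps, not a different
  tolerance knob.
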