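---
title: "Methods: resonance, multistability and energetics in the Huber-Braun neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resonance, multistability and energetics in the Huber-Braun neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hbneuron)
```

## The model

The Huber-Braun (HB) neuron is a four-variable conductance-based model of
thermosensitive peripheral receptors.  The membrane equation

$$C_m \dot V = -I_l - I_d - I_r - I_{sd} - I_{sr} - I_{ext}$$

combines a leak $I_l = g_l (V - V_l)$, two fast spike-generating currents
($I_d$, depolarizing, with instantaneous activation $a_d = a_{d\infty}(V)$;
$I_r$, repolarizing) and two slow subthreshold currents ($I_{sd}$ slow
depolarizing, $I_{sr}$ a simplified calcium-dependent potassium current).
Each ionic current has the form $I_x = \rho\, g_x a_x (V - V_x)$; the
activations of $r$ and $sd$ relax toward sigmoids
$a_{x\infty}(V) = 1/(1 + e^{-s_x (V - V_{0x})})$ at rate $\phi/\tau_x$, and
the slow repolarizing activation integrates the calcium influx driven by
$I_{sd}$:

$$\dot a_{sr} = \phi \, (-\eta I_{sd} - \theta a_{sr}) / \tau_{sr}.$$

Temperature enters only through the van't Hoff factors
$\rho = 1.3^{(T - T_0)/10}$ (conductances) and $\phi = 3^{(T - T_0)/10}$
(kinetics).  All work in this package uses $T = 18$ C against the
reference $T_0 = 25$ C, where the model is excitable with prominent
subthreshold oscillations; `hb_params()` holds the full constant set and
allows any override, including the two Q10 bases.  Units are fixed
package-wide: mV, ms, $\mu$A/cm$^2$, mS/cm$^2$, $\mu$F/cm$^2$; with
$C_m = 1$ the voltage equation is numerically $\dot V = -\sum I$.

The forcing studied throughout is a subthreshold sinusoidal modulation of
a constant bias,

$$I_{ext}(t) = I_0 (1 + B \sin(\omega t)),$$

with $I_0 = 1.5$ above the quiescence current $I^* \approx 1.42$, so that
the instantaneous current never leaves the non-spiking region when
$B < 1 - I^*/I_0 \approx 0.0533$ (`admissible_amplitude_range()`).  Note a
2 percent tension between this bound and the amplitude range
$0 \le B \le 0.0523$ used in the resonance maps of the original study of
this regime; the package exposes the formula and treats the smaller value
as the conventional scan limit rather than reconciling the two.  The phase
convention is $\phi_0 = 0$ at $t = 0$ for every run; frequency-locking
verdicts are insensitive to the phase origin after the transient is
discarded (this is a tested property).

## Integration

All trajectories use the classical fixed-step fourth-order Runge-Kutta
scheme with $dt = 0.01$ ms, the step at which the bifurcation structure of
this model is conventionally computed.  Adaptive or implicit solvers are
deliberately avoided: plateau edges and basin boundaries are sensitive to
step-size policies, and a fixed step makes every run bit-reproducible.
The hot loop is compiled (Rcpp); a long energy run covers $10^8$ steps in
well under a minute.  A pure-R reference step (`rk4_step()`) defines the
scheme and the compiled kernel is tested against it to machine precision;
global fourth-order convergence is verified by Richardson comparison
(halving $dt$ reduces the end-state error by about $16\times$).

Sampling uses a record stride of 10 steps (0.1 ms).  Spike times are not
taken from the stride grid but interpolated linearly at the upward
crossing of $-20$ mV with a 20 ms refractory guard; HB action potentials
overshoot far above 0 mV while subthreshold oscillations stay below about
$-40$ mV, so any threshold in $(-40, 0)$ yields identical trains.

Mean firing frequency is reported in angular units,
$\langle f \rangle = 2\pi (N-1)/(t_N - t_1)$ rad/ms, so that it is
directly comparable to the forcing frequency $\omega$: interspike
intervals near 1000 ms correspond to $\langle f \rangle \approx 0.0063$
rad/ms, and the frequency ratio $\langle f \rangle / \omega$ equals $p/q$
exactly on a $p{:}q$ locking plateau.

## Attractor classification

`classify_attractor()` works from post-transient interspike intervals:
no spikes is subthreshold; an ISI sequence that repeats with period
$k \le 8$ within a relative tolerance of $10^{-2}$ (and at least four
pattern repetitions) is periodic with period $k$; any other firing is
chaotic.  Bursting is simply periodic with $k > 1$ (alternating short and
long intervals); no separate burst detector exists.  The classifier is
invariant to cyclic rotation and to uniform time rescaling of the window,
and periodic verdicts are stable under doubling of the measurement span.
The maximum Lyapunov exponent is the expensive arbiter used to verify
representative attractors, not to label every cell of a basin.

## Continuation and the adaptive residence rule

`continuation_sweep()` follows the firing branch in steps of 0.002
$\mu$A/cm$^2$ with state inheritance.  The residence at each current is
adaptive rather than fixed.  The reason is quantitative: just past the
Hopf point the leading eigenvalue's real part is of order $10^{-6}$ per
ms, so a trajectory inherited from the previous (stable) point needs
$\sim 10^6$ ms to escape the unstable focus, while far from the
bifurcation a verdict is clear within $10^4$ ms.  Any uniform residence
short enough to be affordable reports the firing onset several steps too
low.  Each point therefore integrates until either (a) three spikes have
occurred (spiking), or (b) after a 20 000 ms settle, the block-wise V
amplitude (max minus min over 5 000 ms blocks, about 6 periods of the
subthreshold oscillation) has decreased twice in a row while staying below
spike size (quiescent), with a hard cap of $2 \times 10^6$ ms.  Spiking
points are then measured for 35 000 ms (about 35 interspike intervals) to
estimate $\langle f \rangle$.  With this rule the backward sweep reports
onset at 1.408 and the forward sweep quiescence at 1.420, each within one
step of the linearized Hopf point (1.4085, from the Jacobian eigenvalues)
and the limit-cycle collapse near 1.42.

## Resonance maps and the staircase

Resonance maps evaluate the frequency ratio on a $(B, \omega)$ grid, every
cell from the same stated initial condition with no inheritance, because
the map is explicitly an initial-condition-dependence instrument: the
three canonical states IC1 $=(-60,0,0,0.5)$, IC2 $=(-60,0,0,0.2)$ and
IC3 $=(-20,0,0,0.2)$ give visibly different maps in the multistable
region ($B = 0.0475$, $\omega \in [0.0058, 0.0066]$).

`detect_plateaus()` matches measured ratios to rationals $p/q$ with
$q \le 8$ within $5\times 10^{-3}$ and merges runs of grid points into
plateaus.  In the scans used by the tests, plateau membership is further
restricted to points the classifier labels periodic: cells in the chaotic
windows between plateaus can land numerically near a rational (including
spurious low-denominator matches like $1/3$) without being locked, and
periodicity is what defines a locking.  At $B = 0.049$ a 20-point desk
scan between $\omega = 0.00704$ and $0.00790$ resolves the right edge of
the 1:1 plateau at 0.00718, the onset of the 1:2 plateau at 0.00781, and
an intermediate $n/(n{+}1)$ plateau, in descending Farey order; the
full-resolution staircase (hundreds of points at several times the
window) sharpens the edges but is an hours-long run and is not part of
the default suite.

## Basins and the uncertainty exponent

`compute_basin()` classifies a grid of initial conditions on a 2-D slice
of the 4-D state space under fixed forcing.  The per-cell default is a
$10^4$ ms transient and $3\times 10^4$ ms window at $dt = 0.05$ ms: on 25
random cells of the studied region these labels agree perfectly with
labels from $dt = 0.01$ runs ten times longer, while being two orders of
magnitude cheaper.  These defaults are a deliberate desk-scale choice;
passing a stricter `integration_config` reproduces the reference
behaviour.

The fractal character of the basin boundary is quantified by the
uncertainty-exponent method: the fraction $f(\epsilon)$ of grid points
whose attractor differs from that of the point displaced by $+\epsilon$
along $a_{sr,0}$ scales as $f \propto \epsilon^\alpha$, and
$\alpha < 1$ implies a fractal boundary of dimension $d = 2 - \alpha$ in
the plane.  Two implementation points matter:

* $\epsilon$ must be aligned with the grid spacing so that the perturbed
  partner is itself a grid point; the test grid is therefore anisotropic,
  fine along the perturbation axis (121 columns over
  $a_{sr,0} \in [0.11, 0.145]$, 16 rows across $a_{sd,0}$), giving eight
  $\epsilon$ values from $2.9\times 10^{-4}$ to $2.3\times 10^{-3}$;
* the fit must stay out of the saturation regime: on a coarse isotropic
  grid the large-$\epsilon$ points flatten toward $f \approx 0.5$ and
  bias $\alpha$ downward (an effect we measured directly: an isotropic
  $41\times 41$ grid yields $\alpha \approx 0.43$ purely from
  saturation, while the anisotropic grid recovers
  $\alpha \approx 0.69$ with $R^2 > 0.99$, bracketing the full-scale
  value of about 0.745 from $401 \times 401$ cells, which is a
  cluster-scale computation).

`uncertainty_exponent()` itself is validated on noiseless synthetic
power laws (exact recovery), on a smooth half-plane boundary
($\alpha \to 1$), and on a scrambled random basin ($\alpha \to 0$).

## Lyapunov exponents

`max_lyapunov()` implements the Benettin two-trajectory method in the
4-D state space, the forcing entering both trajectories as shared
explicit time.  The companion starts $\delta_0 = 10^{-8}$ away in a norm
that rescales V by $1/100$ to balance millivolts against dimensionless
activations, and is pulled back to $\delta_0$ every 10 ms; the exponent
is the time-average of the log stretch factors.  Defaults
($10^5$ ms transient, $10^6$ ms accumulation) were chosen so the
stable-focus case reproduces the linearization: at constant
$I_{ext} = 1.5$ the estimate converges to the leading eigenvalue's real
part ($-7.3\times 10^{-4}$ per ms) within a few percent, which is the
closed-form anchor for the method.  The test suite uses a
$3\times 10^5$ ms accumulation for the six coexisting-attractor runs;
at that span the estimates are stable to well under the
$\pm 5\times 10^{-4}$ per ms comparison band (e.g. $+0.00047$ for the
chaotic attractor at $\omega = 0.00585$ versus $+0.00047$ at
$10^6$ ms).

## Energetics

The equivalent-circuit power balance splits as
$\dot H = -V I_{ext} + E_c$ with

$$E_c = -\Big[g_l (V - V_l)^2 + \sum_x \rho\, g_x a_x (V - V_x)^2\Big] \le 0,$$

the metabolic consumption rate of the ion channels; $\mu$A/cm$^2 \times$
mV $=$ nW/cm$^2$, so averages are reported in nJ/s per cm$^2$ of membrane
with no conversion factor.  `energy_rate()` computes $\dot H$
independently from its defining sum, so the identity is an algebraic
cross-check exercised on random states.  Averages use the trapezoid rule
on the 0.1 ms sample grid; $E_c$ is smooth at that resolution, and for
forced regimes the window is rounded down to a whole number of forcing
periods to suppress windowing bias.  At a fixed point $E_c$ is constant,
so the quiescent average has a closed form, and the simulated average
agrees with it to $10^{-6}$ relative -- the package's strictest
end-to-end consistency check.  For stationary regimes short windows
converge: the quiescent average is reproduced after a
$3\times 10^4$ ms transient, and the forced non-firing reference at
$\omega = 0.008135$, $B = 0.049$ (a context value for the base
amplitude, as the original comparison does not restate $B$) changes by
under 0.1 percent between $2\times 10^5$ and $5\times 10^5$ ms
transients.

## Problem sizes in the default suite

Tests are sized for a single CPU: continuation sweeps over
$[1.39, 1.45]$, a 20-point staircase scan, six attractor runs with
$3\times 10^5$ ms Lyapunov accumulation, and a $121\times 16$ basin.
The acceptance script uses the full $10^6$ ms Lyapunov accumulation and
the $5\times 10^5$ ms energy transient.  Full-scale reproductions (the
$401\times 401$ basin, hundreds-of-points staircases at
$5\times 10^5$ ms per point) are hours-to-days of compute and are
documented here rather than run.

## What the fixtures do and do not show

The synthetic fixtures (`make_fixture()`) validate the analysis layer
with analytically known answers: $k$-periodic and logistic-map ISI
sequences for the classifier, stripe and power-law basins for the
uncertainty machinery, damped-sinusoid ringdowns for the spectral
tooling.  They contain no integrator output, so passing them says
nothing about the vector field; conversely the simulation tests anchor
the integrator against closed forms (linearization frequency, fixed-point
energy) independently of the classifiers.  Only the acceptance-level
tests combine the two layers.

## Known limitations

* The model omits chloride and explicit calcium currents and all
  inactivation mechanisms; it is a minimal thermosensitive-receptor
  caricature, not a detailed cortical neuron.
* Classification near basin boundaries at desk-scale windows inherits a
  small mislabel rate; the uncertainty exponent is robust to it only
  while mislabels are rare (they enter $f(\epsilon)$ as an
  $\epsilon$-independent floor).
* The Lyapunov comparison values are method-sensitive in their third
  significant figure; only sign and magnitude are meaningful at desk
  scale.
* No noise, no networks, no temperature sweeps: temperature is a fixed
  parameter here, and stochastic or coupled extensions are out of scope.
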