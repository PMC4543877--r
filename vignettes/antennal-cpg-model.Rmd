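---
title: "A two-level CPG model of antennal tactile exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-level CPG model of antennal tactile exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antennaCPG)
```

## The model

Walking stick insects explore the space ahead of them with rhythmic,
coordinated movements of their two antennae. Each antenna has two actuated
hinge joints — head–scape (HS, proximal) and scape–pedicel (SP, distal) —
with slanted, non-orthogonal rotation axes, and the head adds a yaw degree
of freedom at the neck. The movements are *quasi-rhythmic*: cycle frequency
and amplitude vary from cycle to cycle, yet the two joints of an antenna
keep a stable phase relationship, with the SP joint leading the HS joint by
roughly 20 degrees. `antennaCPG` implements a central-pattern-generator
(CPG) account of this behaviour with two network levels per joint.

**Rhythm generation.** Each joint is driven by a Hopf oscillator in polar
form, with radius $r_i$ (the oscillation amplitude in degrees), unwrapped
phase $\theta_i$, and a separate offset state $c_i$:

$$\dot r_i = \gamma_i (\mu_i^2 - r_i^2)\, r_i, \qquad
  \dot\theta_i = 2\pi v_i + \sum_j w_{ij} \sin(\theta_j - \theta_i - \phi_{ij}), \qquad
  \dot c_i = \gamma^c_i (C_i - c_i).$$

The Hopf form is convenient because amplitude ($\mu_i$), frequency ($v_i$)
and phase relations ($\phi_{ij}$) are independent dials. Five oscillators
form a chain — left SP, left HS, neck, right HS, right SP — with strong
intra-antennal coupling ($w = 20\,\mathrm{s^{-1}}$) and weak coupling
through the neck ($w = 1\,\mathrm{s^{-1}}$). The phase biases lock each SP
20 degrees ahead of its HS and place the two HS joints in anti-phase across
the neck. The weight asymmetry matters: the strong intra-antennal edges pin
the SP–HS difference tightly (its circular variance stays far below the
0.15 working criterion), while the weak neck edges leave the two antennae
largely independent.

**Pattern formation.** A harmonic oscillator output would be a sine; real
joint-angle waveforms are not. Each oscillator therefore feeds its phase
through a pattern-formation network: a truncated Fourier series fitted to a
joint-angle recording on a $T = 5.12$ s window sampled at 50 Hz (256
points, harmonic spacing $1/T \approx 0.195$ Hz). The first $L = 16$
harmonics are retained; the drive signal of joint $i$ is

$$x_i = c_i + r_i\, F_i(\theta_i), \qquad
  F_i(\theta) = M_i \sum_{n=0}^{L} \left[a_n \cos(n\Psi) + b_n \sin(n\Psi)\right],$$

with pattern phase $\Psi = \theta / n_{dom}$. The index $n_{dom}$ is the
dominant harmonic of the fitted window (bin 8 at the natural cycle
frequency, $8/5.12 = 1.5625$ Hz). This phase convention is an
interpretation we make explicit: the scaling by $1/n_{dom}$ is the only
reading under which the dominant component of the output oscillates at the
oscillator's intrinsic frequency (1.45 Hz nominal for the antennal joints)
while the full pattern period spans $n_{dom}$ cycles, i.e. exactly the
length of the analysis window at the natural rhythm. The scaling $M_i$
normalizes the peak magnitude of $F_i$ to 1 (unit peak, not unit power), so
that $\mu_i$ is the half-range of the drive in degrees. The DC coefficient
is fitted but excluded from $F$: the mean posture is carried by $c_i$
alone, which avoids counting the offset twice.

Fitted patterns are *phase-aligned* before use: a pure time shift rotates
the spectrum so that the dominant harmonic is a zero-phase sine. Without
this, the SP-vs-HS lead present in the fitting window would enter the model
twice — once through the oscillator bias $\phi_{ij}$ and once through the
patterns' absolute phases.

**Skeleton and actuation.** The drive signals are targets for
velocity-servo joints: angular velocity equal to $K(x_i - \text{angle})$,
clamped at a maximum rate. This abstraction (gain $K = 350\,\mathrm{s^{-1}}$,
rate limit 2500 deg/s by default) stands in for motor/muscle dynamics; the
gain is chosen so the tracking error is negligible against the working
ranges (about 0.3–0.4 deg RMSE for the HS joint on the standard run, well
inside the 1.5 deg contract; the discrete update is stable for
$K\,\Delta t < 2$). Segment masses are carried as metadata only — no
inertial dynamics are computed, which is deliberate: the phenomena of
interest are properties of the coupled oscillator system, not of limb
mechanics. Forward kinematics composes the neck, HS and SP rotations about
the tabulated pivots and slanted axes (axes co-rotate with their proximal
joints, the only physically consistent reading of an initial-posture axis
table) and places the antennal tip 263 mm further along the distal
direction. The right side mirrors the left across the sagittal plane
(pivot and axis y-components negated), so a mirrored posture corresponds
to sign-inverted right-side angles — which is why the right-side offsets
$C_i$ enter with inverted sign.

## Parameters

| Parameter | HS | SP | Neck | Units | Meaning |
|---|---|---|---|---|---|
| $v_i$ | 1.45 ± 0.05 | 1.45 ± 0.05 | 1.25 ± 0.02 | Hz | intrinsic frequency (± = per-cycle redraw SD) |
| $\mu_i$ intact | 39 (U 8 / L 9) | 31 (U 9 / L 15) | 6 (U 1 / L 1) | deg | amplitude; U/L = SDs of the upper/lower bound draws |
| $\mu_i$ ablated | 55 (U 16 / L 12) | 50 (U 13 / L 18) | 6 (U 1 / L 1) | deg | as above, after dorsal hair-field ablation |
| $C_i$ intact | −60 | 22 | 0 | deg | offset (left side; right side sign-inverted) |
| $C_i$ ablated | −72 | 15 | 0 | deg | offset after ablation |
| $\gamma_i = \gamma^c_i$ | 20 | 20 | 50 | s$^{-1}$ | convergence gains |

Couplings: $\phi_{12} = -\pi/9$, $w_{12} = w_{21} = 20$;
$\phi_{23} = -\pi/3$, $w_{23} = w_{32} = 1$; $\phi_{34} = 4\pi/3$,
$w_{34} = w_{43} = 1$; $\phi_{45} = \pi/9$, $w_{45} = w_{54} = 20$
(stored internally as the target difference $\theta_b - \theta_a$ per
chain pair). The *ablated* condition differs from *intact* only in the
amplitude statistics and offsets — the experiment layer asserts this by
diffing the resolved networks.

## Stochasticity schedule

The quasi-rhythmicity enters through three per-cycle redraws, all driven
by one seedable RNG stream:

* the **upper** effective amplitude bound is redrawn from
  $\mathcal N(\mu, U)$ at each upward zero-crossing of $F$, the **lower**
  bound from $\mathcal N(\mu, L)$ at each downward crossing, both
  truncated at 0 (a negative radius is meaningless in polar form). The two
  bounds gate the positive and negative excursions of $F$ independently,
  switching exactly at $F = 0$ so the drive stays continuous;
* the **intrinsic frequency** is redrawn from $\mathcal N(v, v_{sd})$ once
  per completed oscillator cycle;
* for the `Mmsd` pattern variant, the component **magnitudes** are redrawn
  once per cycle (see below).

Redrawing at cycle events rather than continuously produces cycle-to-cycle
variability of peaks and troughs — which is what the U/L statistics
describe — without intra-cycle discontinuities.

## Pattern variants

Three pattern-formation parameterizations are compared by the experiment
layer. `Mc` uses the spectrum of one representative trial. `Mm` uses the
population-mean amplitude spectrum; since averaging complex coefficients
across trials with unrelated phases would cancel, `Mm` combines the mean
magnitudes with the representative trial's phase spectrum, isolating the
effect of magnitude averaging. `Mmsd` adds zero-mean normal perturbations
with the population SD to each component magnitude (phases kept, truncated
at 0, renormalized), redrawn once per cycle so that the variability acts
*within* a trial — a single per-trial draw would still produce a stable
(if odd) coordination pattern, not the within-trial loss of coupling this
variant is meant to exhibit. Because the population SDs pool across
animals whose dominant components sit in different bins, `Mmsd` effectively
scrambles the waveform from cycle to cycle, and its mean cross-correlogram
peak drops below that of `Mc`/`Mm` — the degradation the suite asserts as
an ordering.

Two further drive waveforms probe phase sensitivity in isolation:
`make_triangular()` (four odd harmonics of the dominant frequency, sines
only — a single-phase spectrum) and `make_augmented_triangular()` (the
same magnitudes duplicated into cosines — a two-phase spectrum). A note on
symmetry: because both stacks live on odd harmonics of the oscillator
phase, half-wave antisymmetry $F(\theta + \pi) = -F(\theta)$ holds for
*any* phase spectrum; what the added cosines break is the time-reversal
symmetry about the waveform peaks (the flanks skew), and that is the
property the tests assert.

## The synthetic data generator

The kinematic recordings behind the original parameter tables are not
published, so the package generates surrogate data with the documented
statistical structure, and everything downstream (pattern fitting, the
`Mm`/`Mmsd` summaries, the analysis suite) is exercised on those. One
trial is built as follows: a shared base phase accumulates at a frequency
redrawn per cycle ($\mathcal N(f_{dom}, 0.05\ \mathrm{Hz})$); each joint
evaluates its own harmonic stack on that phase, SP shifted 20 degrees
ahead; each half-cycle is scaled by a bound draw with the joint's U/L
statistics. Harmonic magnitudes decay away from the dominant bin as
$0.25/(|n - n_{dom}| + 1) + 0.02$ over harmonics 1..20 — a one-time
choice of a plausible spread; nothing downstream is sensitive to its exact
form, and the constants are config-exposed. Side-component *phases* are
drawn independently per joint: the two joints of a real antenna differ in
their phase spectra, and that dissimilarity is precisely what makes the
inter-joint phase lead behaviourally consequential, so the generator must
not produce identically shaped HS and SP waveforms.

A population (`generate_population()`, default 5 animals × 2 trials) draws
each animal's dominant bin from {7, 8, 9, 10} (1.37–1.95 Hz) with mass
0.2/0.5/0.2/0.1, the first animal pinned to bin 8 as the representative
individual, so that the population-mean spectrum remains dominated by the
~1.56 Hz component while per-animal dominants span the observed range.

What the generator does *not* emulate: contact-induced pattern changes,
slow drifts of posture, inter-joint amplitude correlations, and any
individual animal's actual waveform. Tests that pass on this surrogate
demonstrate that the pipeline recovers what the generator encodes (the
imposed lead, the amplitude statistics, the spectral layout) — not that
the model fits any particular animal.

## Numerical choices

* **Integration**: fixed-step explicit midpoint (RK2) at $\Delta t = 5$ ms
  for the coupled system; drive, servo and events update every step.
* **Radial stiffness**: with degree-scaled amplitudes the literal radial
  equation has a relaxation rate $2\gamma\mu^2 \sim 6\times10^4\,
  \mathrm{s^{-1}}$ — unstable under any explicit method at 5 ms. The
  integrator therefore advances the normalized radius $\rho = r/\mu$
  ($\dot\rho = \gamma(1-\rho^2)\rho$, rate $2\gamma$), which has the same
  fixed point $r = \mu$; the literal form remains available
  (`radial_mode = "raw"`, and `hopf_fixed_point()` integrates it with an
  adaptive stable step). A guard aborts if $|\rho|$ exceeds 10 (i.e.
  $10\mu$), diagnosing an inappropriate step size.
* **Initialization**: $r(0) = \mu/2$, $c(0) = C$, phases uniform at random
  (an `"aligned"` mode starts on the bias profile); the first 5 s are
  discarded everywhere before analysis.
* **Normalization**: the pattern peak is located on a 16384-point grid and
  polished by Newton iteration on $F'(\Psi) = 0$, so $\max|F| = 1$ holds to
  machine precision.
* **Correlograms**: ±1 s lag grid at the 50 Hz sample spacing, one-sample
  window stride; windows whose lag-shifted counterpart would leave the
  trace are dropped (zero-padding would attenuate the mean correlogram);
  zero-variance windows yield NA and are excluded from the mean. The peak
  is refined by a parabolic fit through three points and converted to
  phase at the dominant spectral bin of the reference trace (not a
  hard-coded frequency).
* **Angles**: degrees at all API boundaries, radians internally; positions
  in metres; oscillator phases stored unwrapped and wrapped only for
  pattern evaluation and circular statistics.

## Problem sizes

The standard protocol simulates 60 s per trial after the 5 s transient
(~85 locked cycles at the network's compromise frequency of ~1.41 Hz —
the neck's slower intrinsic rate pulls the antennal oscillators slightly
below 1.45 Hz), which stabilizes the mean correlogram and the working-range
percentiles; the test suite uses 10–30 s where convergence is faster and
the full 60 s where a claim concerns steady-state statistics. Phase sweeps
cover −40 to 180 degrees with one 60 s trial per lead.

## Known limitations

* The trajectory *shape ratio* (minor/major axis of the projected
  tip-point covariance) quantifies elongation, not pattern integrity. It
  cleanly detects the collapse to a line under single-phase drive at 0 or
  180 degrees, and it resolves the lead/lag asymmetry around the natural
  20-degree lead (reversed leads give flatter clouds). But a trajectory
  that degrades into an irregular, space-filling scribble *raises* the
  ratio — the covariance of a round cloud is isotropic — so the ratio near
  quadrature leads exceeds the natural-lead value even though the movement
  pattern there is visibly degraded. A cycle-consistency metric would be
  needed to score that kind of degradation; the package reports the ratio
  and the mean-correlogram peak side by side for this reason.
* The neck's intrinsic frequency (1.25 Hz) detunes the chain: with weak
  neck couplings the locked differences across those edges shift by
  $\arcsin((\omega_N - \omega_A)/2.5)$ ≈ 30 degrees relative to the
  nominal biases, and the common frequency settles near 1.41 Hz. Left-right
  symmetry keeps the HS–HS separation at exactly 180 degrees regardless;
  exact bias composition along the chain holds only with equal intrinsic
  frequencies (`equal_frequencies = TRUE`).
* Sensory feedback is implicit: ablation is modelled purely as a change of
  amplitude/offset parameters. Contact events, muscle dynamics, head pitch
  and gravity are out of scope.

## A worked run

```{r, eval = FALSE}
trial <- simulate_trial(default_network("intact"), default_patterns("Mc"),
                        duration = 60, transient = 5, seed = 1)
hs <- trial$angles[, "HS_left"]; sp <- trial$angles[, "SP_left"]
cg <- sliding_crosscorr(hs, sp, fs = trial$fs)
peak_phase(cg, dominant_frequency(hs, fs = trial$fs))  # ~18-19 deg SP lead
working_range(hs)                                      # ~[-84, -30] deg
trajectory_shape(trial$tips_left)$ratio                # ~0.3
```
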