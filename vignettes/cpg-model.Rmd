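---
title: "A bilateral half-center CPG model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bilateral half-center CPG model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cpgcoord` simulates a reduced spinal locomotor central pattern
generator for a pair of hindlimbs.  Each limb is controlled by a rhythm
generator (RG) made of two mutually inhibiting *half-centers* — a
flexor and an extensor population — and the two RGs interact through
two lumped commissural pathways: reciprocal inhibition between the
flexor half-centers (F–F inhibition) and crossed inhibition from each
extensor half-center onto the contralateral flexor (E–F inhibition).

Each half-center is an activity-based population unit.  Its membrane
potential $V$ (mV) and persistent-sodium inactivation gate
$h \in [0,1]$ obey

$$C\,\dot V = -g_L (V-E_L) - g_{NaP}\, m_\infty(V)\, h\,(V-E_{Na}) - I_{syn},$$
$$\tau_h(V)\,\dot h = h_\infty(V) - h,$$

with instantaneous activation
$m_\infty(V) = \left(1+e^{(V-V_{m})/k_{m}}\right)^{-1}$ ($k_m<0$),
inactivation
$h_\infty(V) = \left(1+e^{(V-V_{h})/k_{h}}\right)^{-1}$ ($k_h>0$), and
$\tau_h(V) = \tau_{max}/\cosh\!\big((V-V_\tau)/k_\tau\big)$.
The synaptic current of unit $i$ is
$$I_{syn,i} = d_i\,(V_i - E_{ex}) + \sum_{j=1}^4 b_{ji}\, f(V_j)\,(V_i - E_{inh}),$$
where $d_i$ is the excitatory drive conductance and
$f(V)$ the piecewise-linear normalized rate, 0 below $V_{min}$, 1 above
$V_{max}$.  Units are mV, ms, nS, pF and pA throughout, so the voltage
equation is dimensionally consistent without hidden scale factors.

Slow inactivation of the persistent sodium current makes each unit a
*conditional burster*: quiescent at low drive, intrinsically bursting
in an intermediate drive window, tonically active at high drive
(`classify_unit_mode()` measures this directly).

### Parameters

The reference parameter set (defaults of `unit_params()`,
`network_config()` and `drive_config()`):

| symbol | value | meaning |
|---|---|---|
| `C` | 20 pF | membrane capacitance |
| `g_L`, `E_L` | 2.8 nS, -65 mV | leak conductance and reversal |
| `g_NaP`, `E_Na` | 5 nS, 50 mV | persistent-Na conductance and reversal |
| `V_mNaP`, `k_mNaP` | -40, -6 mV | activation half-voltage, slope |
| `V_hNaP`, `k_hNaP` | -50, 10 mV | inactivation half-voltage, slope |
| `tau_NaP_max` | 1500 ms | peak inactivation time constant |
| `V_tauNaP`, `k_tauNaP` | -100, 40 mV | time-constant voltage dependence |
| `V_min`, `V_max` | -50, 0 mV | rate-function threshold and saturation |
| `E_ex`, `E_inh` | -10, -90 mV | synaptic reversal potentials |
| `b13 = b24` | 1 nS | within-RG flexor-to-extensor inhibition |
| `b31 = b42` | 0.5 nS | within-RG extensor-to-flexor inhibition |
| `b12 = b21` (F–F) | 0.4 nS | reference commissural flexor inhibition |
| `b41 = b32` (E–F) | 0.2 nS | reference crossed extensor-to-flexor inhibition |
| `D_E0` | 1.4 nS | gross extensor drive |

The time-constant scale enters the dynamics only through its magnitude:
a negative relaxation time would make the gate equation divergent, so
`load_config()` takes the magnitude of a negative `tauNaP` with a
warning.

### The drive-coupling rule and the choice of `D_E0`

The drive to each flexor half-center doubles as inhibition of the
ipsilateral extensor: the net extensor drive is $D_{E0} - d_F$, floored
at 0 with a warning (a negative conductance is unphysical).  The gross
extensor drive $D_{E0}$ is a free constant of the coupling rule.  We
fix $D_{E0} = 1.4$ nS so that the flexor and net extensor drives are
equal at $d_F = 0.7$, the midpoint of the upper operating range; the
coupling slope is 1 (a pure difference of conductances).  Both choices
are configuration fields (`drive_config()`), not constants, and the
uncoupled control (`coupled = FALSE`) replaces the rule with fixed
extensor drives (0.7 nS by default).

## Measurement conventions

The analysis layer operates on the normalized rate `f` of each unit;
because `f` is normalized, all thresholds are dimensionless and
parameter-independent.

* **Burst detection** (`detect_bursts()`): onset when `f` crosses 0.10
  upward, offset when it crosses 0.05 downward.  The hysteresis avoids
  chatter near the rate threshold `V_min`.  Partial bursts at window
  edges are discarded.
* **Transient and horizon**: the first 10 s of every run are discarded;
  the default horizon is 40 s, at least a dozen cycles at the slowest
  frequencies of interest (~0.4 Hz).  Coordination-ratio analyses use
  an 80 s horizon so that ten slow cycles are available even when
  cross-inhibition slows the slow side further.
* **Cycle metrics** (`cycle_metrics()`): period = mean onset-to-onset
  interval; flexion = mean burst length; extension = period − flexion;
  a run whose last five periods have a coefficient of variation above
  2% is flagged irregular.
* **Phase difference** (`phase_difference()`): for each left-flexor
  onset, the fractional latency of the next right-flexor onset within
  the left cycle; circular mean and SD over cycles.
* **Coordination ratio** (`coordination_ratio()`): fast-flexor onsets
  are counted within each slow cycle; a 1:n label requires the same
  integer count in at least 90% of ≥10 cycles, anything less consistent
  is *intermittent* — boundary cells are never silently coerced into a
  neighboring class.

### Regime classification

`classify_symmetric()` bins the measured phase $\varphi$:
*anti-phase* if $|\varphi - 0.5| < 0.05$; *in-phase* if the lag
$\min(\varphi, 1-\varphi) < 0.05$; *small phase lag* for lags in
$[0.05, 0.2)$; *asymmetric alternation* otherwise.  The lag is taken
symmetrically in $\varphi \mapsto 1-\varphi$ because the left-right
mirror symmetry of the network makes the two directions equivalent.

Bistability is probed with two seeds.  The anti-phase seed depolarizes
one flexor (−30 mV, everything else −65 mV, gates at
$h_\infty(V)$).  The in-phase seed depolarizes both flexors — but with
a deliberate 1 mV left-right asymmetry: exactly symmetric initial
conditions lie on the invariant synchrony manifold of a symmetric
configuration, so a numerically exact in-phase start could never
reveal that the in-phase solution is unstable.  A point whose two
seeds settle to distinct classes is labeled *bistable*.

The reference commissural point used for all asymmetric-drive
experiments is F–F = 0.4, E–F = 0.2.  Of the two possible readings of
an (x, y) weight pair this is the one that lies in the monostable
anti-phase region at every drive tested (0.3–0.65), which is the
defining requirement for the reference point; `classify_symmetric()`
at this point is the validation (both seeds anti-phase).

## Numerics

The right-hand side is compiled C (`src/cpg_rhs.c`), integrated with
`deSolve::lsoda` at `rtol = atol = 1e-8` and sampled every 1 ms
regardless of the solver's internal steps.  Two independent paths
guard the implementation: a pure-R evaluation of the vector field
(`cpg_derivatives()`, also the unit-test oracle against a literal
transcription of the equations) and a fixed-step RK4 integrator at
0.05 ms.  Adaptive and fixed-step metrics agree to better than 0.5% on
representative runs, and trajectories respect $h \in [0,1]$ and
$V \in [-90, 50]$ mV.

Grid resolutions: 0.01 nS for drive sweeps, 0.02 nS for fast-drive
ratio sweeps, 0.05 nS for two-dimensional maps (the boundary claims of
interest are stated to two decimals).  These sizes keep the full test
suite and the acceptance script at desk scale (tens of seconds to a
few minutes on one CPU).

```{r, eval = FALSE}
library(cpgcoord)
sw <- single_rg_sweep(seq(0.2, 0.8, by = 0.01))
plot(sw)
equal_phase_drive(sw)
```

## What the model does and does not reproduce

Computed behaviors (all recomputed by `scripts/acceptance.R` and the
test suite):

* Isolated-RG frequency grows from ≈0.47 Hz at drive 0.2 to ≈1.45 Hz
  at 0.8, almost entirely by shortening extension while flexion stays
  comparatively flat — the flexor-driven-to-balanced transition.
* Equal drives: exact anti-phase alternation at the reference
  commissural point at all drives; asymmetric alternation at weak E–F
  inhibition and low drive; in-phase synchronization at weak F–F and
  strong E–F; a bistable band between the in-phase and anti-phase
  regions whose upper edge (the transition to pure anti-phase) stays
  put within one grid step across drives at low E–F inhibition, while
  the in-phase region grows with drive and the low-drive asymmetric
  region disappears by drive 0.4.
* Unequal drives: 1:1 phase locking with a lengthening fast-side
  flexion and near-constant period over the slow 0.5 / fast 0.5→0.8
  sweep; 1:2+ coordination only below slow drive 0.45; a maximal order
  of 1:2 at slow drive 0.4 and 1:4 at slow drive 0.25, with
  intermittent cells between locked regions.  Removing the drive
  coupling reverses the split-belt adjustment: fast flexion stays
  constant and both periods fall.

Two measured behaviors deviate from the idealized expectations built
into the model's rationale, and we report them rather than tune them
away:

* The flexion–extension crossover of the single RG sits near drive
  0.57, not at the drive-equality point 0.7.  With the asymmetric
  within-RG inhibition (flexor→extensor 1 nS vs extensor→flexor
  0.5 nS) the flexor dominates at equal excitation — flexion exceeds
  extension by ~150 ms at $d_F = 0.7$ for any coupling constant — so
  duration equality occurs where the extensor still receives more
  drive than the flexor.  Exact coincidence of the two points would
  require symmetric within-RG weights.  For the same reason the
  crossover also appears (near 0.52) in the uncoupled control.
* Frequency is not globally monotone in drive: it peaks near drive
  0.68 and declines slightly toward 0.8 as the growing flexion starts
  to lengthen the period.

## Limitations

The units are population-rate abstractions: no spiking, no
heterogeneity, no noise; bistability is probed from two canonical
seeds rather than by basin exploration; maps are brute-force grids, so
region boundaries are resolved only to one grid step and no
continuation of limit cycles is attempted.  Sensory feedback, supraspinal
control and the full commissural interneuron circuitry (V0, V3, V1
populations) are outside the model's scope — their net effects are
lumped into the two commissural weights and the drive-coupling rule.
Synthetic traces from `generate_fixture()` emulate planted burst
schedules with optional Gaussian rate noise for validating the
measurement layer; they do not emulate the autocorrelated fluctuations
of physiological recordings, so passing detector tests bounds
algorithmic, not biological, error.
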