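# cpgcoord

Simulation and analysis of a reduced bilateral locomotor central
pattern generator (CPG): two flexor–extensor half-center rhythm
generators (RGs), one per hindlimb, coupled by commissural inhibition.
The package is aimed at researchers studying spinal rhythm generation
and interlimb coordination who want a small, fully scripted model in
which tied-belt-like (equal drives) and split-belt-like (unequal
drives) locomotor conditions can be explored quantitatively.

## The model

Each half-center is an activity-based population unit with a
persistent-sodium current whose slow inactivation paces intrinsic
bursting:

    C dV/dt = -I_L - I_NaP - I_syn
    I_L     = g_L (V - E_L)
    I_NaP   = g_NaP m_inf(V) h (V - E_Na)
    tau_h(V) dh/dt = h_inf(V) - h

with sigmoidal `m_inf`, `h_inf`, a sech-shaped `tau_h`, and a
piecewise-linear rate function `f(V)` mapping voltage to normalized
firing rate between `V_min = -50` mV and `V_max = 0` mV.  The synaptic
current of unit *i* is

    I_syn,i = d_i (V_i - E_ex) + sum_j b_ji f(V_j) (V_i - E_inh)

over the four units (left/right flexor, left/right extensor).  Within
each RG the flexor and extensor inhibit each other (`b_FE = 1`,
`b_EF = 0.5` nS); between sides the flexors inhibit each other (F–F
inhibition) and each extensor inhibits the contralateral flexor
(crossed E–F inhibition).

The key structural assumption is *drive coupling*: the excitatory
drive `d_F` to each flexor also inhibits the ipsilateral extensor, so
the net extensor drive is `D_E0 - d_F` with gross extensor drive
`D_E0 = 1.4` nS.  Increasing the flexor drive therefore moves each RG
from flexor-driven rhythmicity (intrinsically bursting flexor, tonic
extensor; short flexion, long extension) toward classical half-center
oscillation (quasi-balanced phases).

## Worked example

```r
library(cpgcoord)

# isolated single RG at low drive: flexor-driven slow bursting
tr <- simulate_cpg(network_config(FF = 0, EF = 0), drive_config(0.2),
                   duration = 40000)
cycle_metrics(detect_bursts(tr, unit = 1))
#> period 2115.2 ms (0.473 Hz), flexion 368.4 ms, extension 1746.8 ms, duty 0.174
#> 13 cycles, period CV 0.0002 (regular)
```

At drive 0.2 the RG bursts at 0.47 Hz with a short flexor burst
(368 ms) and a long extensor phase (1747 ms) — the flexor-driven
regime.  At drive 0.8 the same call reports 1.45 Hz with flexion
(493 ms) now exceeding extension (199 ms): the pattern has inverted,
as during fast locomotion.

```r
# symmetric two-RG model at the reference commissural weights
classify_symmetric(0.3, FF = 0.4, EF = 0.3)$label
#> [1] "anti_phase"

# split-belt-like extreme condition: slow side at drive 0.25
sw <- max_ratio_sweep(0.25, fast_step = 0.05)
attr(sw, "max_n")
#> [1] 4
```

With equal drives the two RGs lock in exact anti-phase (left–right
alternation).  When the slow side is held at drive 0.25 and the fast
side is driven up, the model passes through 1:1, 1:2, 1:3 and 1:4
coordination — four fast-side steps per slow-side step — before the
fast flexor saturates.

Other entry points: `single_rg_sweep()` / `equal_phase_drive()` (drive
dependence of period, flexion, extension), `frequency_map()`
(two-parameter drive plane), `symmetric_regime_map()` (anti-phase /
in-phase / bistable / asymmetric partitions), `asymmetric_ratio_map()`
and `split_belt_sweep()` (1:n coordination), `load_config()` and
`inst/scripts/cpg_tool.R` (file-driven runs from the shell).

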