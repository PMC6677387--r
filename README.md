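# v1scale

Scaling and synaptic compensation in a conductance-based spiking network
model of macaque V1 layer 4Cα.

## What this package is for

Realistic cortical models are built at true cell density — ~36,000 leaky
integrate-and-fire neurons for just 9 hypercolumns of the input layer of
macaque primary visual cortex. A *1/n-cortex* keeps the same architecture
and the same distance-dependent connection probabilities with only 1/n of
the neurons per layer, so every neuron loses all but 1/n of its recurrent
inputs while its feedforward (LGN and ambient) drive is unchanged. This
package is a laboratory for studying what that downscaling does and how to
repair it. It provides:

- seeded **network construction** at any scale 1/n (pinwheel orientation
  map, 6 LGN template wedges per hypercolumn, distance-dependent E/I and
  Layer-6 connectivity, complex-cell subpopulation);
- **external drive** generators: drifting-grating LGN input (rectified
  sinusoid, inhomogeneous Poisson), 350 Hz ambient pulse trains, and
  orientation-tuned Layer-6 feedback;
- a fast **LIF network simulator** (Rcpp core, 0.01 ms steps) for the
  membrane equation `dv/dt = -g_R v - g_E(t)(v - V_E) - g_I(t)(v - V_I)`
  with AMPA/NMDA/GABA kernels, synaptic failures, and source-resolved
  current recording;
- the **compensation algorithm**: current differences `diff_E` and `diff_I`
  (total E-current minus I-current into E and I cells) are steered to their
  full-size values (~60, ~120) by multipliers `m_{Q'Q}(n)` on the synaptic
  weights — an algebraic Step 1 (`step1_solve()`), iterative target
  adjustment (`step2_adjust()`, `compensate()`), an `m_II` simulation scan
  (`scan_m_II()`), and an OS-raising weight exchange (`step3_exchange()`) —
  plus the firing-rate acceptance criteria (`check_acceptance()`) and the
  printed compensated regimes (`table1_multipliers()`);
- **metrics**: orientation/spatial-frequency tuning surfaces, circular
  variance, modulation ratio (F1/F0, simple vs complex), population
  spike-count spectra and gamma-band detection, preference histograms over
  overlapping analysis wedges, rate-distribution bimodality, and
  excitatory-current decomposition by source.

## Worked example

One trial of a compensated 1/16-cortex under the printed multiplier set
(m_EE, m_EI, m_IE, m_II, m_I,LGN) = (1, 2.36, 1.18, 0.7, 1.4): a fresh
2,285-neuron network is built from the seed, driven for 7 s by a
high-contrast vertical grating (2.5 c/deg, 4 Hz) and for 7 s by the
background condition, and summarized over the last 5 s.

```r
library(v1scale)
trial <- scaled_trial(16, table1_row(16), seed = 21)
trial$rates
#> rates (spikes/s): opt E 16.63 / I 43.92; ortho E 6.86 / I 34.63; bg E 1.59 / I 6.50; OS = 2.43
trial$currents_opt
#> Current decomposition (29 E, 8 I cells, window [2, 7] s)
#>   into E cells: LGN 36.4; ambient 14.9; L4 14.8; L6 3.39; I 26.5
#>     excitatory fractions: LGN 52.4%, ambient 21.5%, L4 21.3%, L6 4.9%
#>   into I cells: LGN 71.7; ambient 14.7; L4 18.7; L6 1.86; I 6.24
#>     excitatory fractions: LGN 67.0%, ambient 13.8%, L4 17.4%, L6 1.7%
#>   diff_E = 43, diff_I = 101
```

Reading this: the optimally driven patch fires near the full-size operating
point (E ≈ 13–16 spikes/s is the acceptance band) while the orthogonal
patch stays low; more than half of the excitatory current into these E
cells now arrives from LGN rather than from cortex — the signature of the
reduced cortex turning into a feedforward relay. Patch statistics at this
scale rest on ~30 E cells, so individual trials scatter; the scaling
experiments average five seeded networks per condition. The uncompensated
catastrophe is one call away:

```r
scaled_trial(9, seed = 21, conditions = "driven")$rates
#> optimal-patch E rates ~200 spikes/s, orientation selectivity lost
```

A command-line front end over the same functions is in
`inst/cli/v1scale.R` (verbs: `build-network`, `simulate`, `compensate`,
`metrics`, `run-experiment`, `make-fixture`).

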