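# tcmdbs

A spiking-network simulator of deep brain stimulation (DBS) acting on a
thalamo-cortical microcircuit, for computational neuroscientists studying
why high-frequency (~130 Hz) stimulation desynchronizes pathological
cortical activity while low-frequency (~20 Hz) stimulation does not.

The model contains 540 subthreshold, noise-driven Izhikevich neurons in
six populations — three excitatory cortical layers (S, M, D, 100 neurons
each), shared cortical interneurons (CI, 100), and the thalamocortical
relay (TCR, 100) and thalamic reticular (TRN, 40) nuclei — coupled
all-to-all by Tsodyks–Markram short-term plastic synapses with conduction
delays. Membrane dynamics follow

    dv/dt = 0.04 v² + 5v − u + 140 + I,   du/dt = a(bv − u),
    if v ≥ v_p + ζ(t):  v → c,  u → u + d,

where the input current `I` sums a bias, the delayed weighted
postsynaptic currents of all presynaptic neurons, Gaussian membrane noise
ξ(t), an optional Poissonian background term, and — in the deep cortical
layer D only — a periodic rectangular DBS current. Synapses track
utilization `u` and resources `x` per presynaptic neuron in facilitating
/ depressing / pseudo-linear classes; their periodic-drive steady state
has a closed form (`tm_steady_state()`) under which depressing synapses
transmit ~6× less at 130 Hz than at 20 Hz — the synaptic-suppression
mechanism at the core of the high-frequency DBS effect.

Analysis utilities quantify the network state: Golomb–Hansel population
synchrony χ on smoothed per-neuron spike signals, a binned-spike-count
LFP proxy, and Welch beta-band (13–30 Hz) power, compared across pre-DBS
and DBS epochs.

## Worked example

The default configuration is the reference protocol: 12 s at dt = 0.1 ms,
membrane noise sd 0.5, threshold noise sd 0.1, Poissonian background
disabled, and 130 Hz DBS into layer D from second 6.

```r
library(tcmdbs)
cfg <- default_config(seed = 1)
res <- simulate(cfg)
res
#> Simulation result: 63405 spikes from 540 neurons over 12 s (dt 0.1 ms, seed 1 , engine cpp )
#>   spikes per structure: S=11159, M=12080, D=36420, CI=3205, TRN=269, TCR=272

compare_epochs(res, structures = c("S", "M", "D", "CI"))
#> Epoch metrics (baseline: pre )
#>  epoch t_start_ms t_end_ms structure    chi rate_hz beta_power total_power
#>    pre       1000     6000         S 0.6232   9.362    1.29310      4.2844
#>    pre       1000     6000         M 0.6190  10.166    1.53411      4.9507
#>    pre       1000     6000         D 0.6003   9.300    1.16434      3.9213
#>    pre       1000     6000        CI 0.3535   3.072    0.11640      0.6024
#>    dbs       7000    12000         S 0.2869   9.188    0.14337      1.3212
#>    dbs       7000    12000         M 0.2546   9.864    0.15148      1.3335
#>    dbs       7000    12000         D 0.1238  51.090    0.02039     63.2860
#>    dbs       7000    12000        CI 0.1318   1.990    0.01070      0.2042
#> Ratios vs baseline:
#>  epoch structure chi_ratio beta_ratio
#>    dbs         S    0.4604    0.11088
#>    dbs         M    0.4114    0.09874
#>    dbs         D    0.2062    0.01751
#>    dbs        CI    0.3728    0.09192
```

Before stimulation the cortex sits in a parkinsonian-like state:
synchronized population bursts (χ ≈ 0.6) with elevated beta-band power.
During 130 Hz DBS, layer D fires tonically at ~51 Hz but its depressed
synapses transmit little; the burst rhythm collapses — synchrony falls to
roughly a third of baseline and beta power to ~10%. Re-running with
`cfg$dbs$frequency_hz <- 20` instead *entrains* the network (χ stays
near baseline and beta power rises), reproducing the characteristic
contrast between low- and high-frequency stimulation.
`raster_plot(res, "raster.png")` draws the spike raster with the DBS
onset marked, and

```r
reproduce_dbs_contrast("dbs_out", seeds = 1:5)
```

runs the full paired-seed 20 vs 130 Hz experiment, writing rasters, a
metrics table and a plain-text summary.

A command-line front end wraps the same workflows:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/tcm.R", package="tcmdbs"))') \
    simulate --out run1 --seed 1
```

with subcommands `config`, `simulate`, `analyze`, `plot-raster` and
`reproduce-dbs-contrast`.

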