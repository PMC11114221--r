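# aosim

Simulation of a receptor-based artificial olfactory system: from
odorant-specific receptor-channel conductance responses to device-constrained
neural-network odor recognition.

## The problem

Bioelectronic noses pair human olfactory receptors (hOR51E1, hOR51E2,
hOR52D1), hosted in nanodiscs on graphene gates, with organic synaptic
devices. Each receptor channel answers an odorant with a characteristic
maximum conductance *G*<sub>max</sub>; the triple of channel responses is a
combinatorial receptor code that distinguishes even homologous short-chain
fatty acids — propionic (PA), butyric (BA), valeric (VA) and hexanoic (HA)
acid — and their mixtures. `aosim` is for researchers in neuromorphic sensing
who want this whole computational chain as reproducible, tested code:

1. **Synaptic device** — saturating-exponential LTP/LTD conductance curves
   *G*<sub>LTP</sub>(*P*) = *B*[1 − e<sup>−*P*/*A*</sup>] + *G*<sub>min</sub>
   with *B* = (*G*<sub>max</sub> − *G*<sub>min</sub>)/[1 −
   e<sup>−*P*<sub>max</sub>/*A*</sup>], nonlinearity fitting, EPSC relaxation,
   paired-pulse facilitation.
2. **Synthetic sensing data** — seeded channel x odorant response generator
   (measured PA responses 170.3/146.1/119.6 uS at 3 ppm; synthetic,
   rank-preserving defaults elsewhere), linear concentration calibration, and
   the theoretical 1/*n* equimolar mixture rule.
3. **Pattern refinement** — segmentation of the conductance axis into nine
   regions and binarization into 9 x 3 one-hot-per-channel patterns
   (216/40 train/inference patterns for singles, 2194/366 for mixtures).
4. **Device-aware ANN** — a 27 x 14 x 4 (singles) or 27 x 27 x 9 (mixtures)
   two-layer perceptron whose synapses are differential conductance pairs
   updated only by integer potentiation pulses along the device's LTP curve
   (learning rates 0.03 / 0.0001, pulse cap, saturation refresh).
5. **Sensor statistics** — ΔF/F0 quenching normalization, PCA of response
   patterns, 3σ/S detection limits, mixture combinatorics.

## Worked example

```r
library(aosim)

res <- run_pipeline("single", out_dir = "run1", seed = 7)
res$trajectory[1:3, ]
#>   step accuracy_pct
#> 1    0            0
#> 2  100          100
#> 3  200          100
res$final_accuracy
#> [1] 100
round(range(res$detection_limits$lod_ppm), 2)
#> [1] 0.22 1.17
```

The run synthesizes 216 training and 40 inference response patterns for the
four acids at 3 ppm, bins them into 9 x 3 binary grids, trains the
device-aware 27 x 14 x 4 network for 1000 steps, and records inference
accuracy every 100-step epoch: recognition reaches 100% within the first
epoch and stays there. Detection limits (3σ/S per channel-odorant pair) fall
in the sub-ppm to ~1 ppm range. The mixed-odorant task,
`run_pipeline("mixed", ...)`, trains the 27 x 27 x 9 network for 150,000
steps on the nine equimolar mixture classes; its accuracy climbs into the
low 90s (e.g. final 91.5%, peak 92.1% at seed 11).

Individual stages are plain functions: `simulate_ltpd_cycle()` /
`fit_nonlinearity()` for device traces, `sample_responses()` /
`build_datasets()` for data, `init_network()` / `train_ann()` /
`evaluate_ann()` / `linearity_sweep()` for the network, `pca_responses()` /
`detection_limit()` / `quench_norm()` for statistics. See the methods
vignette (`vignettes/artificial-olfaction.Rmd`) for the model and every
design decision.

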