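# smfret

Hidden Markov analysis of single-molecule FRET trajectories, built for
conformational-landscape studies of membrane receptors (the packaged
presets model the chemokine receptors CXCR4 and ACKR3 in nanodiscs).

Single-molecule FRET records two fluorescence channels — donor `I_D` and
acceptor `I_A` — per molecule over time. The apparent FRET efficiency
`E_app = I_A / (I_A + I_D)` tracks the distance between the labeled
helices, so a receptor switching among discrete conformations produces a
trajectory that hops among discrete FRET levels until a dye photobleaches.
`smfret` turns collections of such traces into a landscape:

1. **Correction & screening** — background/bleed-through correction,
   change-point photobleach detection (acceptor-only vs simultaneous
   two-channel loss), and an automated single-molecule screen (exactly one
   bleach step, anti-correlated channels, sufficient pre-bleach length).
2. **Global HMM** — all accepted trajectories of a condition are fit
   jointly by one K-state hidden Markov model with Gaussian emissions
   `N(mu_k, sigma^2)` sharing a single variance across states, trained by
   Baum–Welch and idealized by Viterbi decoding (C++ recursions, scaled,
   underflow-free).
3. **State-count selection** — for K = 2..5, the pooled `E_app`
   distribution is fit by a Gaussian mixture initialized from the HMM;
   `BIC = p ln n − 2 ln L` (p = 3K − 1) is summed over conditions and the
   selected K minimizes it among candidates whose peak positions are
   consistent across conditions.
4. **Landscape summaries** — state populations from Viterbi occupancy,
   per-state composite KDE histograms (Gaussian kernel, bandwidth 0.04),
   transition density probability (TDP) maps over (FRET before, FRET
   after) with dwell-averaged coordinates, censored dwell-time tables,
   and condition-to-condition population shifts in percentage points.

Because raw microscope recordings for studies of this kind are typically
not deposited, the package includes a synthetic trace generator with full
ground truth (Markov state paths, anti-correlated channels with a constant
photon budget, bleed-through, backgrounds, stochastic photobleaching) and
six study-condition presets; every stage of the pipeline is validated by
recovering known generative parameters.

## Worked example

Simulate an apo-ACKR3-like experiment (4 states at E_app 0.85 / 0.66 /
0.39 / 0.11, near-uniform occupancy, sequential transitions, shared
sigma 0.08), screen it, fit the global HMM, and summarize:

```r
library(smfret)

exp <- simulate_experiment("apo-ACKR3", n_traces = 80, n_frames = 300, seed = 42)
scr <- screen_experiment(exp)
#> accepted 80 / 80 traces

fit <- em_fit(scr$trajectories, K = 4)
fit
#> smFRET global fit: K = 4, 80 trajectories / 8880 frames, 9 EM iterations (converged)
#> smFRET HMM: 4 states, sigma = 0.0825
#>   means: 0.852 0.660 0.390 0.106
#>   A diag: 0.966 0.935 0.939 0.971

paths <- viterbi_all(scr$trajectories, fit$model)
state_populations(paths, 4, condition = "apo-ACKR3")
#> State populations [apo-ACKR3] (80 traces, 8880 frames):
#>   0.274 0.266 0.238 0.222

tdp <- build_tdp(extract_transitions(scr$trajectories, paths))
tdp
#> TDP grid: 392 transitions, sigma = 0.030, 6 peak(s)

dwell_times(paths, 4)
#> Completed dwell times by state:
#>  state count   mean_s rate_per_s
#>      1    51 2.154902  0.4640582
#>      2   124 1.476613  0.6772256
#>      3   103 1.354369  0.7383513
#>      4    42 2.742857  0.3645833
```

The fitted means land on the generative values to ±0.01, the shared
emission SD (0.0825) matches the injected 0.08, occupancies are near the
uniform stationary distribution, the six TDP peaks are exactly the
sequential (adjacent-state) transitions in both directions, and dwells are
seconds-scale. `select_state_count()` runs the same fits across K = 2..5
and both criteria of step 3; `run_pipeline()` drives
simulate → screen → fit → report with serialized, hash-stamped outputs
(see `?run_config`, and `inst/scripts/smfret.R` for a shell entry point).

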