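# tacdelay

Single-voxel tracer arrival delay estimation for dynamic PET.

Kinetic modeling of dynamic PET needs the tissue time-activity curve
(TAC) and the blood input function aligned in time: tracer arrives at
every tissue at a different moment than at the aorta where the input
function is measured, and an uncorrected transport delay biases the
fitted rate constants. Long-axial field-of-view scanners acquire
whole-body dynamics at ~1 s frame rates, making per-voxel delay maps
possible — if the estimator survives single-voxel noise.

`tacdelay` implements a noise-robust onset estimator for that setting.
Each curve is cumulatively summed with frame-spacing weights
(suppressing zero-mean frame noise), the summed curve

A<sub>Σ</sub>(t) = a·b·ln[e^((c−t)/b) + 1] + a·(t − c)

— the integral of the logistic a / (1 + e^((c−t)/b)) — is fitted over
up to 10 data-driven ranges after plateau removal, accepted fits are
filtered (R² ≥ 0.8, positive onset before the range end) and the
median of the best half gives the onset time

T = c − 3.5·b.

The delay between a tissue curve and the input function is the
difference of their independently estimated onsets,
ΔT = T<sub>tissue</sub> − T<sub>input</sub>. Two standard comparators
are included — full cross-correlation, and a one-tissue compartment
model (dC<sub>T</sub>/dt = K₁·C<sub>A</sub>(t−Δ) − k₂·C<sub>T</sub>)
with jointly fitted delay — together with a synthetic one-tissue
benchmark and voxelwise delay-map generation with a 5×5×5
neighbourhood fallback for failed voxels.

## Worked example

Simulate a tissue curve from the one-tissue model (K₁ = 50
ml/100g/min, k₂ = 1 min⁻¹) with a true arrival delay of 4 s behind a
gamma-variate bolus input, then estimate that delay three ways:

```r
library(tacdelay)

sched  <- h2o_schedule()                      # 54 frames, 0-180 s
idif   <- input_tac(input_preset("h2o_idif"), sched)
tissue <- simulate_tissue(
  simulation_spec(K1 = 50, k2 = 1, delay = 4, sigma = 0, seed = 1))

onset_fit(idif)
#> Cumulative-sum onset fit
#>   plateau corrected: end index 13, level 21.07 Bq.s/ml
#>   fits: 5 attempted, 4 accepted
#>   onset time: 12.114 s

estimate_delay(tissue, idif)                  # proposed method
#> [1] 5.606501

xcorr_delay(tissue, idif)                     # cross-correlation
#> [1] 19

one_tissue_fit(tissue, idif)                  # compartment comparator
#> One-tissue compartment fit with incorporated delay
#>   K1 = 50.06 ml/(100 g min), k2 = 1.005 1/min, delay = 4.01 s
#>   rss = 215.597 over 54 frames (endtime 180 s)
```

The input onset lands on the bolus arrival (12 s, estimated 12.1 s).
The proposed method reads the delay about 1.6 s too large — the
systematic offset of onset-difference estimators on smooth
convolution-shaped tissue curves, uniform across the parameter map and
quantified by the benchmark below. Cross-correlation aligns the tissue
peak with the input peak and overshoots to 19 s; the one-tissue fit,
which shares the simulator's model family, recovers the truth almost
exactly on noise-free data. Their relative standing reverses with
noise: `run_benchmark()` reproduces the full residual-delay maps and
histograms across the K₁ × k₂ × delay × σ grid.

Voxelwise maps on 4D volumes (NIfTI + BIDS-style timing sidecar):

```r
pet <- read_dynamic_pet("dyn.nii.gz", "dyn.json")
dm  <- voxelwise_delay_map(pet$volume, pet$schedule, idif,
                           body_mask = mask, method = "onset")
write_delay_map(dm, "delay.nii.gz", reference = pet$header)
```

A thin command-line wrapper with the same capabilities is installed at
`inst/cli/tacdelay` (subcommands `estimate`, `simulate`, `delay-map`,
`benchmark`).

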