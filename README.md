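# sarvop

Virtual observation point (VOP) compression of 10 g-averaged local SAR
matrices for multi-channel (parallel-transmit) MRI arrays, with
overestimation strategies that control the maximum *relative*
overestimation.

## The problem

A parallel-transmit array drives each channel with an independent complex
weight, the excitation vector `b`. The 10 g-averaged SAR at voxel `v` is
the quadratic form `b' S_v b` of a Hermitian positive-semidefinite matrix
`S_v` (W/kg per unit input power); safety supervision needs
`max_v b' S_v b` over millions of voxels for every pulse. VOP compression
replaces the full set by a small subset plus an overestimation term:

    max_{v in V_all} b' S_v b  <=  max_{w in V_sub} b' S_w b + omega(b)   for all b,

so only the subset ever has to be evaluated. The bound must never
underestimate; the slack `omega` decides where overestimation lands.
`sarvop` implements the greedy matrix-dominance compression with four
interchangeable overestimation terms:

| strategy | `omega(b)` | behavior |
|---|---|---|
| `global` | `eps_G * b' S_Global b` | reference; absolute overestimation roughly flat |
| `diag`   | `eps_G * b' (dI) b`, `d` = worst-case SAR | exactly constant at unit power |
| `local`  | `eps_G * b' S_local b`, a local-SAR-tracking matrix | relative overestimation controlled |
| `double` | `eps_G * (max_u b' S_u b + eps_G_pre * b' S_Global b)` over a small pre-computed VOP set | overestimation is itself a VOP bound |

Every discarded voxel carries a *dominance certificate*: nonnegative,
L1-normalized coefficients proving `S_v <= sum_w c_w S_w + Omega` as a PSD
matrix inequality, which guarantees the scalar bound for every excitation
vector. The package also ships a synthetic multi-channel SAR-field
generator (hot spots, ball averaging, global-SAR matrix), a
random-excitation evaluation harness that certifies the
no-underestimation guarantee, an HDF5 container format, and a CLI.

## Worked example

```r
library(sarvop)

spec <- array_phantom_spec(n_channels = 8, grid_shape = c(14, 14, 14),
                           layout = "local", seed = 42)
set <- generate_sar_set(spec)
set
#> <sar_matrix_set> 2744 voxels x 8 channels, with global-SAR matrix
#>   worst-case SAR: 2.74714 W/kg per unit power

# build the local-SAR-tracking overestimation matrix and size its factor so
# that the median overestimation term is 10 % of the worst-case SAR
model <- build_model(set, "local", epsilon_g = 1, seed = 1)
model$epsilon_g <- epsilon_for_term_fraction(set, model, fraction = 0.1)

res <- compress(set, model,
                compression_config(epsilon_g = model$epsilon_g, seed = 1))
res
#> <vop_result> 19 VOPs from 2744 voxels (strategy local, epsilon_g = 0.553048)

B <- random_unit_power_vectors(2e4, 8, seed = 7)
evaluate_compression(set, res, B)
#> <evaluation_report> 20000 vectors, strategy local, 19 VOPs
#>   max relative overestimation: 296.267 %
#>   max absolute overestimation: 0.690317 W/kg
#>   underestimations: 0
```

2744 matrices collapse to 19 VOPs. For each of the 20 000 random
unit-power excitation vectors the VOP bound is at least the true maximum
local SAR (`underestimations: 0` — any violation would be a hard error,
not a report line); the worst case over probes costs a 296 % relative
(0.69 W/kg absolute) overestimation. Tightening `fraction` trades VOP
count against overestimation; `comparison_curve()` scans that trade-off
across strategies, and `plot_comparison_curves()` draws the resulting
"maximum relative overestimation versus number of VOPs" figure.

The same pipeline is available from a shell via the `inst/cli/sarvop`
script (`simulate`, `compress`, `evaluate`, `compare`, `export-baked`
subcommands on an HDF5 container).

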