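# slicerecon

Reconstruction of densely sliced CT volumes from sparsely sliced input,
in R. Abdominal CT is usually anisotropic — ~1 mm in-plane voxels but
slice increments of 2.5 mm or more — and the missing through-plane
resolution blurs organ boundaries exactly where radiotherapy dose
calculation needs them. Acquiring thinner slices raises dose; this
package instead *synthesizes* the missing slices.

For an interpolation factor `m` (half-integers allowed), the dense stack
`S_1 … S_n` is related to its sparse subsequence `S_1, S_{1+2m}, …` by
gaps of `2m − 1` missing slices. slicerecon reconstructs every gap from
its two neighbouring slices and merges the results with the untouched
originals. Its core is a **parallel architecture**: `2m − 1`
independently parameterized U-nets, each consuming the same two-slice
input and each dedicated to one target position, so reconstructed slices
cannot influence one another. For a specific organ, a **range-clip
transform**

    f(x) = 0 if x < R_ll;  1 if x > R_lh;  B (x − C) otherwise,
    with C = R_ll and B = 1/(R_lh − R_ll),

stretches the organ's narrow normalized intensity range `[R_ll, R_lh]`
(estimated from labeled training data only) onto [0, 1]; a second model
trained on f-transformed data reconstructs the organ, and its
inverse-transformed output replaces the base prediction inside the organ
mask (**organ-oriented reconstruction**). Evaluation follows the
protocol of per-position MAE in Hounsfield units, per-slice-normalized
SSIM, improvement percentages, paired Wilcoxon tests, and a threshold
rule for choosing `m`. A seeded synthetic phantom generator (narrow
organ intensity ranges, nonlinear through-plane organ drift, stomach air
pocket, aligned labels) makes the whole pipeline trainable and testable
without patient data.

## Worked example

The end-to-end phantom experiment — generate 30 labeled phantoms
(64×64×25), train the parallel model (m = 2, three branches) and a liver
range-clip model on the 24 training volumes, reconstruct the 6 held-out
volumes, evaluate — is one call:

```r
library(slicerecon)
st <- phantom_study(seed = 1)
st$report$averages
#>           method   mae_hu      ssim
#> 1         linear 30.19680 0.7850377
#> 2       parallel 24.15366 0.8409250
#> 3 organ_oriented 22.46399 0.8600231
round(unlist(st$metrics[c("improvement_vs_linear_pct",
                          "p_parallel_vs_linear",
                          "organ_mae_base_hu", "organ_mae_oo_hu")]), 4)
#> improvement_vs_linear_pct      p_parallel_vs_linear
#>                   20.0124                    0.0000
#>         organ_mae_base_hu           organ_mae_oo_hu
#>                   23.1281                   12.3319
```

Reading: linear interpolation errs by 30.2 HU on the held-out target
slices; the trained parallel model cuts that to 24.2 HU (20.0 % better,
Wilcoxon p ≈ 2e−19 on per-slice errors), and inside the liver the
organ-oriented merge nearly halves the base model's error (23.1 → 12.3
HU). The run takes ~6 minutes on one CPU.

Individual pieces compose the same way from the command line:

```sh
inst/cli/slicerecon phantom --out runs/data --n-volumes 30 --seed 1
inst/cli/slicerecon train --data runs/data --out runs/model \
    --targets-per-gap 3 --epochs 10 --organ liver --seed 1
inst/cli/slicerecon reconstruct --input sparse.nii.gz --out dense.nii.gz \
    --method parallel --manifest runs/model/manifest.json
inst/cli/slicerecon select-m --table maxmae.csv --mu 15
```

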