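# chimic

Maximal information coefficient (MIC) estimation with a chi-square-terminated
grid search, for exploratory detection of functional and non-functional
dependences between paired numeric variables.

## The problem

The MIC of a paired sample D of n points is

    MIC(x, y) = max over grid shapes (nx, ny) of  I(x, y) / log2 min(nx, ny)

where I is the mutual information of the nx-by-ny grid induced by
rank-partitioning the two axes. The classical **ApproxMaxMI** search sweeps
every row count r, equipartitions one axis into r bins, and fills the other
axis by dynamic programming over "clump" boundaries, visiting all shapes with
nx·ny below the size bound B(n) = n^a (a = 0.6). Because the search always
runs to the bound, finite independent samples receive substantially nonzero
MIC scores (small-sample bias) and the cost grows quickly with n.

**ChiMIC** replaces the size bound on the optimized axis with a data-driven
stopping rule: column endpoints are inserted one at a time (each the cut that
most increases mutual information given the cuts already accepted), and each
candidate endpoint must reject independence in a chi-square test on the r-by-2
contingency table of the two columns it creates,

    chi2 = sum_ij (|f_ij - n_i T_j / N| - h)^2 / (n_i T_j / N),  df = r - 1,

with Yates continuity correction (h = 1/2) when r = 2 and threshold
p < 0.01. The search stops at the first endpoint that fails, so noise no
longer buys grid cells: noiseless functional relationships still score
MIC = 1, while independent data score near 0 far earlier than under
ApproxMaxMI. The package also provides the **minimum cell number**
complexity statistic,

    MCN(D, eps) = min { log2(nx * ny) : M[nx, ny] >= (1 - eps) * MIC(D) },

seeded generators for the simulation designs used to study these statistics,
and a permutation-null statistical-power harness for arbitrary bivariate
statistics.

## Worked example

```r
library(chimic)

## two-period sinusoid with 50% relative uniform noise
s <- sample_function("sin_two_period", 1000, noise_level = 0.5, seed = 7)

chimic_mic(s)
#> MIC (ChiMIC), n = 1000
#>   mic        : 0.780602
#>   best grid  : 11 x 2
#>   matrix     : 385 computed shapes, B = 63.096
#>   mcn (eps=0): 4.459

approx_max_mi(s)$mic          # 0.851438, best grid 31 x 2
mcn(chimic_mic(s), mode = "one-minus-mic")   # 3
```

The chi-square rule stops the noisy sinusoid at an 11-column grid where the
bound-driven search runs to its full 31-column budget; the extra 20 columns
fit noise, which is why the ApproxMaxMI score is higher on data with no extra
structure. The robust MCN (eps = 1 - MIC) recovers log2(8) = 3, the cell
count of the smallest grid that captures a two-period oscillation.

On a shell, the same computations are available as subcommands:

```sh
Rscript inst/scripts/chimic-cli.R simulate --generator sin_two_period \
    --n 1000 --noise 0.5 --seed 7 --out pairs.tsv
Rscript inst/scripts/chimic-cli.R mic --input pairs.tsv --algorithm chimic
```

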