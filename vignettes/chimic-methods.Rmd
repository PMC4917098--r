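---
title: "Grid-search MIC estimation with chi-square termination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-search MIC estimation with chi-square termination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimic)
```

## The statistic

For a paired sample $D = \{(x_i, y_i)\}_{i=1}^n$, every pair of axis
partitions into $n_x$ and $n_y$ bins induces a contingency grid with mutual
information $I$ (in bits). The maximal information coefficient is

$$\mathrm{MIC}(D) = \max_{n_x, n_y} \frac{I(n_x, n_y)}
{\log_2 \min(n_x, n_y)},$$

a number in $[0, 1]$ that is 1 for noiseless functional relationships and
tends to 0 for independent variables as $n \to \infty$. The per-shape maxima
form the *characteristic matrix* $M[n_x, n_y]$. All partitions act on rank
order only, so every statistic in this package is invariant under strictly
increasing transforms of either margin; this is checked by property tests.

Two searches populate $M$:

* **`approx_max_mi()`** — the dynamic-programming baseline. For each row
  count $r$ from 2 to $\lfloor B/2 \rfloor$ (with $B = n^a$, default
  $a = 0.6$), the y-axis is equipartitioned into $r$ rows and the x-axis is
  optimized by an exact prefix DP over candidate cut positions, for every
  column count up to the per-row budget $B/r$. The sweep is repeated with
  axes swapped and the per-shape maximum kept.
* **`chimic_mic()`** — the chi-square-terminated search. For the same row
  sweep, column endpoints are inserted greedily (each new cut maximizes the
  grid mutual information with all accepted cuts frozen) and every candidate
  endpoint must pass a chi-square independence test on the $r \times 2$
  table of the two columns it creates, at threshold $\alpha$. The first
  failure stops the column search for that row partition. All intermediate
  grids actually visited are scored into $M$.

The complexity statistic `mcn()` is the log2 cell count of the smallest grid
whose score reaches $(1-\varepsilon)\,\mathrm{MIC}$, either at fixed
$\varepsilon$ or with $\varepsilon = 1 - \mathrm{MIC}(D)$ (the robust mode).
Its floor is 2, attained by a $2\times 2$ grid; simple shapes sit near the
floor (2 for linear, $\log_2 6$ for a vertex-centred parabola, 3 for a
two-period sinusoid — recomputed by the test suite and the acceptance
script), while under the bound-driven baseline high noise pushes the
$\varepsilon = 0$ value toward $\log_2 B$, the top of the searched range.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `a` | 0.6 | exponent of the grid-size bound $B(n) = n^a$ |
| `c` | 5 | superclump multiplier: at most $c\,l$ candidate cuts are kept when optimizing toward $l$ columns |
| `budget_rounding` | `"floor"` | how the per-row column budget $B/r$ becomes an integer |
| `alpha` | 0.01 | chi-square threshold for endpoint acceptance |
| `test_first` | `TRUE` | whether the first endpoint is itself tested |
| `apply_b_cap` | `TRUE` | keep the $B$ bound on the *row* sweep (column depth is always governed by the test) |

$\alpha = 0.01$ sits just below 0.0114, the continuity-corrected p-value of
the most extreme $2\times 2$ table whose expected counts reach the classical
minimum of five (counts $\{0,5;5,0\}$); a smaller threshold would demand
more evidence than five-expected-count cells can ever provide.

### Candidate cuts: clumps and superclumps

Only boundaries between *clumps* — maximal runs of consecutive (in x-order)
points lying in the same y-row — can increase mutual information, so both
searches draw candidate cuts from them. When more than $c\,l$ clumps exist,
the candidate set is coarsened by snapping an equipartition's ideal cut
positions onto clump boundaries. ChiMIC uses the same candidate set as the
DP baseline; consequently every grid it visits lies inside the baseline's
search space and its characteristic-matrix entries can never exceed the
baseline's on a shared shape (a property test asserts this entrywise over
seeded samples).

### Conventions where the bound is ambiguous

Published descriptions of the $B(n)$ bound do not fully pin down rounding:
a strict reading admits only $n_x n_y \le B$, while observed reference
outputs include grids one column beyond it (a $2\times 32$ grid at
$n = 1000$, where $B \approx 63.1$). The default here is the strict
`"floor"` budget; `"round"` and `"ceil"` reproduce the laxer behaviour.
`mcn()` applies no additional size filter by default — the matrix already
contains only searched grids — and exposes `b_max` for a strict
$n_x n_y < B$ cut-off.

### Testing the first endpoint

The sequential description of the algorithm tests the $m$-th endpoint only
for $m > 1$. Left untested, however, the first endpoint hands every row
partition a free 2-column grid: on independent data the maximum over all row
sweeps of these untested best-single-cut scores alone inflates the null MIC
to roughly twice the reported behaviour of the method. Testing the first
endpoint against the two columns it creates (so a row partition whose best
single cut cannot already reject independence contributes no grid) restores
the reported null behaviour while leaving every noiseless and MCN anchor
unchanged; it is therefore the default, with `test_first = FALSE` available
as the text-literal variant. When no endpoint anywhere passes, no grid is
accepted and the MIC is reported as 0 with an empty characteristic matrix —
an honest statement that the search found no dependence structure.

## Ties and numerical choices

* Points with equal raw values on an axis are atomic: no cut may separate
  them. Equipartition snaps each ideal cut $i\,n/r$ to the nearest tie-legal
  position (ties toward the smaller position), so the achieved bin count can
  drop below $r$; rank orders use stable sorts so duplicates behave
  deterministically.
* $0 \log 0 = 0$ throughout; all logs are base 2.
* Scores are clamped to $[0, 1]$ against floating-point round-off, and the
  qualifying comparison inside `mcn()` uses a $10^{-12}$ slack so grids that
  attain the MIC up to double-precision noise qualify at $\varepsilon = 0$.
* Best-shape tie-breaks: smallest cell count, then smallest $n_x$.
* Degenerate inputs: an axis with fewer than 2 distinct values yields no
  partition and contributes nothing; samples need $n \ge 4$.

## The synthetic-data module

`independent_pair()` draws i.i.d. uniform pairs — the null configuration.
`sample_function()` implements $Y = f(X) + (U - 0.5)\cdot
\text{level}\cdot\text{RANGE}$ with $U$ uniform on $(0,1)$: centred uniform
noise whose support is exactly `level * RANGE` wide (at level 0.5 on a
unit-range function, residuals lie in $(-0.25, 0.25)$). The catalog mixes
monotone maps (linear, cubic, square root, exponential, logistic) with
non-monotone ones (vertex-centred parabola $4x^2$ on $(-1/2,1/2)$, two- and
four-period sinusoids on $(0,1)$); domains were chosen once so that RANGE is
1 (2 for the sinusoids) and non-monotonicity is interior to the domain.
`sample_power_study()` implements the five power-study relationships (linear,
parabolic, sinusoidal, circular, checkerboard) with Gaussian noise amplitude
$a$; the checkerboard draws uniformly from the 10 solid unit squares
($(i+j)$ even) of a $4\times 5$ board, and the circular relationship uses
independent normal draws for the two coordinates.

All generators are bit-reproducible given `seed` and restore the caller's
RNG state. They emulate the reference simulation designs — independent
nulls, relative-noise function families, and the five power relationships —
and nothing else: real data with heteroskedastic noise, outliers, heavy
ties, or discrete marginals are outside what passing tests demonstrate.

### Random versus designed x

For *population* properties of a noiseless relationship — the minimal grid
that attains MIC = 1, hence the noiseless MCN — random uniform x is
surprisingly fragile: where the curve starts or ends exactly on a row
boundary (the sinusoid at $x = 0$ and $x = 1$), the sample median of $y$
falls a hair above or below the curve's crossing level and a sliver clump of
$O(1)$ points appears at the domain edge, adding one spurious column to the
minimal perfect grid (MCN $\log_2 10$ instead of 3, in most samples). The
generator therefore offers `x_design = "grid"` — the $n$ equispaced domain
midpoints — as the evaluation protocol for such deterministic quantities;
the acceptance script uses it for the noiseless MCN values, and a property
test documents the two attainable random-x outcomes.

## Power estimation

`estimate_power()` follows the permutation protocol: for each condition,
`trials` true datasets are generated and one y-permuted null per true
dataset; the nulls are pooled into a single null distribution, and power is
the fraction of true-statistic values *strictly* exceeding its 0.95 quantile
(type-7). Pooling (rather than per-trial comparison) is a deliberate
reading of the terse protocol; under the null generator itself the estimate
is calibrated near $1 - 0.95$, which the acceptance suite checks within
binomial error. Defaults mirror the reference design — $n = 400$, 500
trials, 25 amplitudes log-spaced in $[1, 10]$ — while the test suite runs a
scaled-down sweep (5 relationships, 3 amplitudes, 100 trials) chosen to keep
the whole suite under a minute while leaving Monte-Carlo error well below
the effect sizes it asserts.

## Problem sizes used by the tests

Unit oracles run exhaustive search at $n \le 12$ where enumeration over all
cut subsets is exact; distributional checks use 500 replicates at
$n \in \{100, 400\}$ (the reference replicate count); noiseless and
saturation anchors use $n = 1000$. The acceptance script completes in a few
seconds and the full test suite in under a minute on one CPU.

## Known limitations

* The exact candidate-coarsening and bound conventions of the original
  Matlab implementations are not recoverable; this package's DP is an exact
  optimizer over its candidate set, which on independent data at larger $n$
  yields a slightly higher null mean than the reference reports
  (see the null-mean computation in `scripts/acceptance.R`).
* ChiMIC's greedy conditional insertion is the reading under which the
  flanking-column test is well defined; a full re-optimization per size
  would test a different (sometimes undefined) "new" endpoint.
* The chi-square rule governs column depth only; the row sweep keeps the
  $B$ cap by default. Disabling it (`apply_b_cap = FALSE`) extends the row
  sweep to $n/2$ and is substantially slower.
* No continuous (non-grid) mutual-information estimation, no density
  estimation, and no alternative optimizers (simulated annealing, parallel
  variants) are provided.
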