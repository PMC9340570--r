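---
title: "Selecting the sparsity of an inferred gene regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the sparsity of an inferred gene regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnic)
```

## The model

Everything in this package lives in the linear steady-state view of gene
regulation. A network of $N$ genes is a weight matrix $A$ with
$A_{ij} \neq 0$ meaning gene $j$ regulates gene $i$; the diagonal holds
self-regulation (degradation), kept strictly negative so the system
$\dot{x} = Ax + p$ is stable. At steady state, the log2 fold-change
response $Y$ to a perturbation design $P$ (one column per experiment,
$-1$ marking the knocked-down gene) satisfies

$$ Y = -A^{-1} P, \qquad \text{equivalently} \qquad A\,Y = -P . $$

Inference methods estimate $A$ from $(Y, P)$; all of them can do so at any
sparsity. A *sparsity sweep* collects one candidate per integer link count
across a range — by convention 1 to 5 links per gene in single-link steps,
which makes 401 candidates for 100 genes. The selection problem is: which
candidate to report?

## GRNIC

Each candidate $A_i$ is scored by $\mathrm{GRNIC}_i = K_i + L_i$ and the
minimizer is selected (ties go to the sparser candidate).

**Penalty $K$.** The raw penalty is the number of distinct regulators:
genes with at least one nonzero off-diagonal outgoing weight. A gene whose
only edge is its self-loop is not a regulator. Raw penalties are min–max
normalized to $[0,1]$ across the sweep.

**Badness of fit $L$.** The candidate reconstructs expression through the
Moore–Penrose pseudoinverse, $\hat{Y}_i = -A_i^{\dagger} P$, which is
well-defined even for the rank-deficient matrices that sparse candidates
usually are. Both $\hat{Y}_i$ and the measured $Y$ are divided by their own
maximum absolute entry — pseudoinverse reconstructions can differ from the
data by orders of magnitude, and this range-matching makes the comparison
scale-free — and the raw error is the root-mean-square of the elementwise
differences. Across the sweep the raw errors are min–max scaled to
$[0,1]$, transformed as $e^{x}$ (the opposite counterpart of taking the
logarithm of a goodness of fit, keeping the criterion as close to AIC's
form as a prediction error allows), and min–max normalized again.

Two arbitrary-looking but load-bearing conventions:

* *Order of operations for $L$*: raw RMS error → min–max scale → exp →
  min–max normalize. The pre-scaling bounds the exponent so the transform
  is comparable across datasets; the post-normalization puts $L$ in the
  same $[0,1]$ range as $K$, without which the two addends are
  incommensurable.
* *Degenerate normalization*: a term that is constant across the sweep
  (including single-candidate sweeps) min–max normalizes to all zeros, so
  it simply drops out of the criterion.

### The singular-value safeguard

Before inverting, singular values of the candidate below a threshold are
zeroed, guarding against unstable inversions. The threshold is
$1/\max(Y)$, and "max" deserves care. `grnic` reads it as the largest
*singular value* of the measured matrix (`threshold_mode = "sigma_max"`,
the default). The reason is structural: any candidate consistent with
$A Y \approx -P$ has singular values of order $1/\sigma(Y)$ and larger, so
a cutoff at $1/\sigma_{\max}(Y)$ sits just below the candidate spectrum and
fires only on genuinely degenerate directions — a guard that is almost
never active, which is what a safeguard should be. The entrywise readings
(`"max_abs"`, `"max"`) are retained as options but behave badly on
steady-state fold-change data, where $1/\max|Y|$ lands in the middle of
every fitted candidate's spectrum: during development this zeroed most
singular values of most candidates, flattened the badness-of-fit curve,
and broke selection outright. If every singular value falls below the
threshold the prediction is all zeros and the candidate is flagged
degenerate.

## The inference backends

All three backends share the sweep contract: candidates on one gene set,
strictly increasing link counts, every integer link count in
$[\mathrm{round}(\text{min\_lpg}\,N),\ \mathrm{round}(\text{max\_lpg}\,N)]$.

**Lasso** fits $A Y = -P$ row by row: network row $i$ is an L1-penalized
regression (no intercept, unstandardized) of $-P_{i\cdot}$ on $Y^{\top}$.
A single log-spaced 200-point penalty grid is shared by all rows, from
just above the smallest penalty with an all-zero solution down to $10^{-4}$
of it. The signed coefficient network is collected at each grid point;
link counts the path skips are filled by weight-cutoff truncation of the
nearest denser path network, so the sweep has per-link granularity.

**Ridge** fits the same model with an L2 penalty at one fixed value
(default 1), which has the closed form
$A = -P\,Y^{\top}(YY^{\top} + \lambda I)^{-1}$ and is fully dense; the
sweep is obtained by keeping the $k$ largest-magnitude off-diagonal
entries for each $k$. Ties at a cutoff break deterministically by
(|weight| descending, regulator index, target index), so builds are
reproducible and keep-$k$ is permutation-equivariant.

**Tree ensembles** fit, for each gene, a regression random forest
predicting that gene's expression from all other genes across experiments
(1000 trees by default, $\sqrt{N-1}$ candidate features per split,
per-gene seeds derived from one user seed). Importance scores are
nonnegative, so the network is positive-weight and unsigned. Edge
direction is *reversed* relative to the usual importance convention — the
predicted gene becomes the regulator — because on knockdown data the
reversed orientation is the more accurate one. The sweep again comes from
weight cutoffs. Exact agreement with any particular forest implementation
is deliberately not part of the contract; only the importance-ranking
interface is.

Unsigned candidates go through the pseudoinverse as-is: selection still
works because the reconstruction only has to *rank* candidates, not be a
calibrated signed model.

## The benchmark simulator

`generate_true_network()` emulates the statistics of curated *E. coli*
subnetworks commonly used for steady-state benchmarks rather than
extracting them: around half the genes are regulators (`tf_fraction`,
default 0.53), true sparsities sit in 1.5–1.95 links per gene, and
regulator choice uses preferential attachment on out-degree to mimic
hub-heavy bacterial topology. Off-diagonal magnitudes are uniform on
$[0.5, 1.5]$ with random sign (the literature prescribes no weight law;
bounded magnitudes keep conditioning sane), diagonals are $-1$, and
interaction weights are damped by a constant factor until the spectral
abscissa is below $-0.01$ *and* the condition number is at most
`condition_max` (default 10).

The conditioning bound is a deliberate design choice. Stability alone
permits condition numbers in the hundreds, and from such systems the
perturbation response carries almost no recoverable information — noise-free
lasso support recovery collapses below F1 0.5. Real benchmark generators
face the same issue and control it (the property is known as
interampatteness in the network-inference literature); capping the
condition number at 10 keeps the inference problem solvable while leaving
it far from trivial.

`make_design()` builds the canonical single-knockdown design: $-I_N$
replicated horizontally, $N \times 3N$ for the standard three replicates.
`simulate_expression()` applies the exact inverse (the truth is
invertible by construction). `add_noise()` adds i.i.d. Gaussian noise
calibrated analytically so that the realized signal-to-noise ratio —
defined as $\sigma_{\min}(Y) / \sigma_{\max}(E)$, tying the noise to the
weakest signal direction — matches the requested SNR in expectation, using
the $\sigma (\sqrt{N} + \sqrt{M})$ concentration of the largest singular
value of a Gaussian matrix. The presets are SNR 10 for "low" noise and 0.1
for "high"; these are this package's documented stand-ins, since no
canonical pair of values exists, and any positive SNR may be passed
directly.

What the simulator does *not* emulate: nonlinear ODE kinetics, saturation,
mRNA/protein distinction, measurement-specific error structure, and
correlated (non-i.i.d.) noise. Passing benchmarks here demonstrates the
selection machinery under the linear steady-state model; performance on
real perturbation compendia must be established separately.

## Evaluation conventions

Edges are compared as directed (regulator, target) pairs, ignoring weight
sign and magnitude — the tree backend is unsigned yet is evaluated on the
same footing — and self-loops never enter any count, so accuracy is
determined solely by actual regulatory links. F1 at zero true positives is
defined as 0. For sanity: in a nested sweep true positives are weakly
increasing in density, and tp + fn is constant at the truth's link count.

## Numerical choices and degenerate inputs

* GRNIC ties select the sparsest candidate (parsimony).
* Keep-$k$ tie-breaking is lexicographic as described above.
* Singular values sitting numerically *at* the safeguard cutoff are
  retained (a $10^{-8}$ relative slack absorbs SVD round-off).
* Zero-variance expression rows cannot act as regulators: lasso excludes
  them (with a warning), forests give them zero importance.
* A zero candidate matrix yields a zero prediction flagged degenerate,
  and a sweep whose source network has too few nonzero weights yields a
  truncated sweep with a warning.
* The ridge penalty (1.0) is configurable; no canonical value exists, and
  the cutoff extraction makes selection insensitive to it over a wide
  range.

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` run the full
pipeline at benchmark sizes chosen to exercise every code path at
meaningful difficulty: five 50-gene networks (true sparsities 1.50–1.94
links/gene, three replicates, low-noise preset, lasso backend) for the
selection-quality checks, 30-gene systems for the noise-trend comparison,
20-gene systems for the shuffle control, and 100-gene sweeps for the
sweep-geometry checks. At these sizes the whole acceptance script
completes in seconds.

## Known limitations

* When the regulator count rises much faster than the badness of fit
  falls, the penalty can dominate and GRNIC selects sparser than the
  accuracy optimum; this is an intrinsic property of the criterion, also
  visible in its behavior on some benchmark draws.
* Selection quality inherits the backend's quality: if no candidate in
  the sweep is accurate, GRNIC can only pick the least bad one.
* The lasso path orientation assumes perturbation-style designs where
  $P$ is informative; observational data without designed perturbations
  are out of scope.
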