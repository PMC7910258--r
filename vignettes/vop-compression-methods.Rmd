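---
title: "VOP compression of local SAR matrices: models, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VOP compression of local SAR matrices: models, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarvop)
```

## The problem

In parallel-transmit (pTx) MRI, every channel of the array is driven with an
independent complex weight, collected in the excitation vector
$b \in \mathbb{C}^{N}$. The 10 g-averaged specific absorption rate at voxel
$v$ is the quadratic form $b' S_v b$ of a Hermitian positive-semidefinite
(PSD) matrix $S_v$ (the *Q-matrix*), in W/kg per unit input power, with $b'$
the conjugate transpose. Regulatory supervision needs
$\max_v b' S_v b$ for every pulse, but an electromagnetic simulation
delivers $10^6$–$10^7$ such matrices — far too many to evaluate in real
time or inside a pulse-design loop.

Virtual observation point (VOP) compression replaces the full set
$V_{\mathrm{all}}$ by a small subset $V_{\mathrm{sub}}$ plus an
*overestimation term* $\omega(b) \ge 0$ such that for **every** excitation
vector

$$\max_{v \in V_{\mathrm{all}}} b' S_v b \;\le\;
  \max_{w \in V_{\mathrm{sub}}} b' S_w b + \omega(b).$$

The bound must never underestimate (safety); the price is overestimation.
How $\omega$ behaves as a function of $b$ decides *where* the
overestimation lands: a term that is flat across excitation vectors wastes
headroom exactly where actual SAR is low, inflating the *relative*
overestimation and needlessly throttling duty cycle (proportionally) or
flip angle (by the square root).

## The four overestimation strategies

All four strategies run through the same greedy compression; they differ
only in $\omega$:

* **`global`** — $\omega(b) = \varepsilon_G\, b' S_{\mathrm{Global}} b$,
  with $S_{\mathrm{Global}}$ the global-SAR matrix (mass-weighted mean of
  the point matrices). The classical choice and the reference standard.
* **`diag`** — $\omega(b) = \varepsilon_G\, b' (d I) b$ with $d$ the
  worst-case SAR (the largest eigenvalue over the whole set). For
  unit-power vectors the term is the constant $\varepsilon_G d$: the
  absolute overestimation is flat versus actual SAR.
* **`local`** — $\omega(b) = \varepsilon_G\, b' S_{\mathrm{local}} b$ with
  $S_{\mathrm{local}}$ a crude local-SAR-tracking matrix built once, ahead
  of the compression (next section).
* **`double`** — $\omega(b) = \varepsilon_G\,(\max_u b' S_u b +
  \varepsilon_{G,\mathrm{pre}}\, b' S_{\mathrm{Global}} b)$ over a small
  pre-calculated VOP set $\{S_u\}$: the overestimation is itself a VOP
  bound, hence tracks actual local SAR more closely than any single
  matrix can.

`local` and `double` are the relative-overestimation-controlling
strategies; `global` and `diag` are the two reference standards.

### Building S_local

`build_s_local()` runs: (i) draw a seeded random subsample of the voxels
(default 1 %, without replacement); (ii) compress the subsample with the
`global` strategy at a fixed inner factor (default 0.2 — the source
describes the construction but not the inner factor, so it is a documented
knob); (iii) sum the resulting VOP matrices into $S_{\mathrm{pre}}$, which
up-weights matrices that represent local SAR; (iv) eigendecompose
$S_{\mathrm{pre}} = V \Lambda V'$; (v) for each eigenvector $v_i$ (a
unit-power excitation) compute the true maximum local SAR
$\mathrm{SAR}_i = \max_v v_i' S_v v_i$ over the **full** set; (vi) set
$d_i = \mathrm{SAR}_i^{1/R}$, and return
$S_{\mathrm{local}} = V \operatorname{diag}(d) V'$.

The exponent $R \ge 1$ compresses the spectrum: `select_R()` picks the
smallest $R$ with $(\max_i \mathrm{SAR}_i / \min_i \mathrm{SAR}_i)^{1/R}
\le 10$, in closed form $R = \max(1, \log_{10}(\max/\min))$. Two numerical
guards: the threshold is implemented as $\le 10$ (a strict inequality has
no closed form and the boundary is immaterial), and eigen-SAR values below
$10^{-6}$ of the maximum are floored there before the power is applied
(rank-deficient $S_{\mathrm{pre}}$ would otherwise make $D$ singular); the
build record flags when flooring happened.

## The greedy compression and its safety argument

Voxels are visited in descending order of largest eigenvalue (ties toward
the smaller voxel id, for deterministic reports). The first voxel enters
$V_{\mathrm{sub}}$. Every later voxel $v$ runs the dominance test:

1. Initialize the coefficients of each set (VOP coefficients, and pre-VOP
   coefficients for `double`) to equal values with L1 norm 1. Coefficients
   are kept nonnegative throughout — the convex-combination reading of the
   L1 condition, which is what makes the PSD argument work.
2. Form $P = \sum_w c_w S_w + \Omega(c) - S_v$, where $\Omega$ is the
   overestimation matrix ($\varepsilon_G Z$, or the $c$-weighted pre-VOP
   combination for `double`). If $\lambda_{\min}(P) \ge
   -\mathrm{tol}\cdot\lambda_{\max}(S_v)$, the voxel is *bounded*: $c$ is
   its certificate and it is discarded.
3. Otherwise let $b$ be the eigenvector of $\lambda_{\min}(P)$. If $b$
   violates the scalar VOP condition, no certificate can exist; the voxel
   is *unbounded* and joins $V_{\mathrm{sub}}$ with $b$ recorded as its
   witness.
4. Otherwise perturb one coefficient at a time (uniform on
   $[0, 2c_k + 1/|c|]$, then L1 renormalization, alternating between the
   two coefficient sets for `double`), keeping changes that do not
   decrease $b'Pb$, until $b'Pb \ge 0$; then return to step 2.
5. After `max_coef_iterations` rounds without resolution the voxel joins
   $V_{\mathrm{sub}}$ anyway — which is always safe.

Safety is voxel-local: VOP members satisfy the bound trivially, and each
discarded voxel carries a convex combination proving
$S_v \preceq \sum_w c_w S_w + \Omega$, which implies the scalar bound for
every $b$. Because new VOPs only ever *add* terms (their coefficients
default to zero in old certificates), certificates never need re-checking
— the suite re-verifies all of them against the final VOP set by an
independent eigendecomposition.

Numerical choices: the PSD acceptance threshold is relative to the
candidate's own scale ($10^{-9}\lambda_{\max}(S_v)$ by default; a hard
$\ge 0$ fails on floating-point noise), and the same absolute tolerance is
used on the other side, in the step-3 violation check. The default 30
outer iterations with $5|c|$ inner proposals is a documented knob (only "a
pre-selected maximum" is prescribed by the algorithm). An alternative
update rule, `greedy_argmax`, jumps all coefficient mass onto the member
with the largest $b'S_w b$ — a single deterministic move that resolves the
failed step-3 inequality — and is offered for speed; the randomized rule
remains the default for fidelity to the published procedure.

Two implementation details matter for scale. First, each voxel's
randomized search runs on its own RNG substream derived from the
configuration seed and the voxel id, so results are independent of how
much work other voxels needed. Second, `compress()` keeps a pool of all
witness vectors found so far and pre-screens each candidate against it: a
candidate whose SAR at any pooled witness already exceeds the bound there
provably has no certificate and is added directly. Because of the
substreams this changes only the work done, never which voxels are
certified — asserted in the suite by comparing pooled and unpooled runs.

### Baking

`bake_vops()` folds the overestimation into directly evaluable
collections: for matrix-term strategies a single collection
$\{S_w + \varepsilon_G Z\}$ whose per-vector maximum *equals* the full
bound (the common additive term commutes with the max); for `double`, two
collections whose maxima are added. Evaluating one baked VOP at 8 channels
costs 72 complex multiplications and 63 complex additions
(`op_count(8)`) in the dense two-stage convention (matrix–vector product,
then inner product) — the package deliberately counts that convention, not
a symmetry-exploiting kernel, as that is how per-VOP supervision cost is
usually quoted.

## Evaluation methodology

`evaluate_compression()` draws isotropic random unit-power excitation
vectors (independent standard complex Gaussian entries, normalized; the
distribution of the probes is not prescribed anywhere authoritative, so
isotropy is the assumption and is recorded with its seed), computes the
actual maximum over the uncompressed set and the baked bound per vector,
and summarizes maximum relative and absolute overestimation. Any
underestimation beyond $10^{-9}$ relative raises a hard error, not a
warning. Evaluation is chunked over vectors; chunking is bit-neutral for
the maxima, which the suite asserts.

`comparison_curve()` scans strategies over a grid of overestimation
factors and reports (number of VOPs, maximum relative overestimation)
per point — for `double` the pre-VOPs are included in the count. Because a
raw $\varepsilon_G$ means different things under different $Z$ matrices,
operating points are anchored with `epsilon_for_term_fraction()`: the
factor is chosen so that the *median* overestimation term over random
unit-power probes equals a target fraction of the worst-case SAR (for
`diag` this reduces exactly to $\varepsilon_G = f$). The median, not the
minimum, is used because a strongly coupled array can have a
near-singular $S_{\mathrm{Global}}$ whose minimal term is not
representative of its size. Cross-strategy comparisons at "matched VOP
budget" pair each reference grid point with the nearest-by-VOP-count
point of the other strategy (`compare_at_matched_vops()`).

## The synthetic SAR-field generator

`generate_sar_set()` emulates the structure the algorithms assume, without
electromagnetics. Per channel $c$, the complex field at voxel $v$ is

$$e_c(v) = A_c\, e^{-\|r_v - r_c\|^2 / 2\sigma^2}\, e^{i\phi \|r_v - r_c\|}
  \;+\; \beta \bar{A}\, e^{i(\phi\, k_c \cdot r_v + \varphi_c)}
  \;+\; \text{noise},$$

a localized Gaussian lobe with propagation-like phase, plus a smooth
volume-filling background wave with a seeded random direction $k_c$ and
phase $\varphi_c$ per channel, plus complex Gaussian noise. The point
matrix is the rank-1 outer product
$Q_v = \kappa\, \overline{e(v)}\, e(v)^{\mathsf T}$; "10 g averaging" is a
fixed-radius ball mass-average of the $Q_v$ (PSD as a convex combination —
the compression is agnostic to how the averaged matrices arose, only the
Hermitian-PSD structure and spatial correlation matter, so adaptive-mass
region growing is deliberately not modeled); the global-SAR matrix is the
mass-weighted mean over all point matrices, so its trace equals the mean
point trace exactly (asserted in the suite).

Defaults, and why ($22^3$ voxels of 5 mm, 8 channels):

* **lobe width** $\sigma$ = 55 mm (local ring at 1.1× the lattice
  half-width) and 200 mm (remote 2 × 4 rings at 2.2×): lobes comparable to
  the array radius let excitations interfere constructively or
  destructively, which is what produces the order-of-magnitude spread
  between worst-case and best-case maximum local SAR that motivates
  relative-overestimation control.
* **phase gradient** $2\pi/300$ rad/mm: an effective wavelength of
  ~30 cm, between in-tissue and free space at 7 T; shorter coherence kills
  the interference depth, longer coherence makes it unrealistically deep.
* **background level** $\beta$ = 0.30 (local) / 0.15 (remote) of the mean
  drive amplitude: the multipath/far-field surrogate that dominates the
  *volume-averaged* (global) SAR while the lobes dominate the *maxima*.
  Without it the global matrix is both unrealistically ill-conditioned
  (a quasi-dark mode) and spuriously correlated with the local maxima.
  A close-fitting array is assigned the larger multipath fraction.
* **noise** 0.5 % of the RMS field: a simulation noise floor, scaled
  relative to the field inside the lattice so that remote layouts (weak
  absolute fields) keep the same signal-to-noise ratio.
* **averaging radius** 2 voxels (10 mm): a 10 g-like ball at this
  resolution; it also sets the rank of the averaged matrices, which tests
  exploit by setting it to 0 for rank-1 regimes.

With these defaults both layouts show worst/best spreads above 10× and an
eigenvector-SAR spread above the rescaling threshold of 10, and the
S_local term correlates more strongly with actual maximum local SAR than
the global term does — the qualitative regime the strategies were designed
for.

What the phantom does **not** reproduce: body-model heterogeneity, coil
tuning/decoupling, and — importantly — the extreme spatial redundancy of
real FDTD datasets ($10^6$–$10^7$ voxels over smooth fields). Two
consequences are worth knowing. First, in this field model the remote
layout's spread does *not* exceed the local layout's (the close ring's
mutual interference dominates at desk scale), although the remote
mechanism — farther elements, wider lobes, weaker multipath — is
implemented as described. Second, compressing the phantom to "10 or fewer"
pre-VOPs for the `double` strategy requires a pre-factor
$\varepsilon_{G,\mathrm{pre}}$ of order 10, not the ~0.1–0.2 a
multi-million-voxel dataset admits; the `double` overestimation term is
correspondingly global-heavy here, which narrows its advantage over
`local`. Passing tests on this phantom therefore certify the safety
machinery, the certificates, and the qualitative strategy behavior — not
the quantitative VOP-count reductions reported for FDTD body data.

## Problem sizes in the test-suite

The suite exercises: core algebra against brute-force oracles at 3–4
channels; compression soundness on 120–300-voxel sets with full
certificate re-verification; safety (zero underestimation over $10^5$
random probes) on $22^3$-voxel 4- and 8-channel phantoms for all four
strategies; and the strategy-comparison methodology on a $12^3$-voxel
remote-layout phantom over five compression seeds with $10^5$ probes.
The comparison set is smaller than the safety sets because it is
compressed 60 times (4 strategies × 3 operating points × 5 seeds); the
phantom's lower redundancy makes each compression substantially more
expensive per voxel than published FDTD datasets, and a $12^3$ set
already exhibits every qualitative feature the comparison probes.

## Known limitations

* The greedy algorithm is not minimal: with a nonzero overestimation term,
  spatial neighbours can retroactively cover an earlier VOP, and the
  iteration cap (step 5) adds voxels whose certificate search merely
  failed. On sets with well-separated extreme matrices every surviving VOP
  is provably necessary (the suite asserts this); on smooth realistic sets
  a minimal-subset post-pass could shrink the result further and is not
  implemented (the published method is greedy by design).
* Certificates prove dominance at the stored coefficients; they are
  checked at a relative PSD tolerance, so "zero underestimation" means
  zero beyond $10^{-9}$ relative.
* The container I/O holds the matrix set in memory (HDF5 datasets are
  chunked on disk); datasets at the $10^7$-voxel scale would need a
  streamed visit order, which is not implemented.
* MATLAB-dialect import of externally produced matrix files is not
  provided; the HDF5 layout documented in `write_container()` is the
  interchange format.

## Reproducibility

Every stochastic step — phantom noise and background, the S_local
subsample, the coefficient search, probe batches — is seeded explicitly,
and compression seeds are decoupled per voxel, so any pipeline rerun with
the same configuration reproduces all reported maxima bit-identically
(asserted in the suite through the command-line interface).
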