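---
title: "Database fingerprints: compressing a compound library into one binary vector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Database fingerprints: compressing a compound library into one binary vector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfptools)
```

## The model

A binary molecular fingerprint represents one molecule as a fixed-length
vector over $\{0,1\}$: position $i$ records the presence of the $i$-th
predefined structural feature (166 positions for MACCS keys, 881 for the
PubChem fingerprint). A library of $n$ molecules is then an $n \times L$
bit matrix $X$. The *database fingerprint* (DFP) compresses the whole
matrix into a single length-$L$ binary vector. For each bit position the
empirical set probability is

$$p_i = \frac{1}{n}\sum_{j=1}^{n} X_{ji},$$

with no smoothing or pseudocounts, and the DFP applies a probability
threshold $t$:

$$\mathrm{DFP}_i = \begin{cases} 1 & p_i > t \\ 0 & p_i \le t.\end{cases}$$

The inequality is deliberately strict: a bit sitting exactly on the
threshold is off (`build_dfp()` enforces this and the tests pin it). Because
the DFP depends on $X$ only through $p$, it is invariant to duplicating the
library, and for a single molecule it reproduces that molecule's
fingerprint at any $t < 1$. Raising $t$ can only clear bits, so DFP support
is antitone in the threshold — the basis for the shrinking significant-bit
counts seen when the cutoff is raised from 0.5 to 0.6 to 0.7.

Three threshold strategies are implemented:

* **fixed** — a user cutoff; 0.5 is the default for the PubChem workflow,
  where higher cutoffs visibly reduce the resolution between libraries.
* **random_reference_mean** — the mean per-bit probability of a seeded
  random reference population (by default 1500 vectors of 166 independent
  Bernoulli(0.5) bits). For unbiased bits this concentrates near 0.5 within
  $3\sqrt{0.25/(1500 \cdot 166)} \approx 0.003$; the historical value used
  with MACCS keys, 0.55, came from an external random source and is
  accepted as a given constant rather than something a calibrated generator
  reproduces.
* **mean_plus_sd** — the library's own mean probability plus one sample
  standard deviation over the $L$ positions (denominator $L-1$; the
  population/sample choice is a convention this package fixes explicitly),
  clipped below 1 so the DFP cannot be forced all-zero.

Thresholds $\ge 1$ are rejected outright: they would produce an
information-free all-zero fingerprint and almost certainly indicate user
error.

## Entropy as a diversity metric

The per-bit Shannon entropy of the profile is used as a library diversity
score. The default **binary** mode uses the full Bernoulli entropy
$H(p) = -p\log_2 p - (1-p)\log_2(1-p)$ (maximum 1 bit at $p = 1/2$); the
**ones_term** mode keeps only $-p\log_2 p$ (maximum $\log_2(e)/e \approx
0.531$ at $p = 1/e$). The total SE is the sum over positions. The field's
reported SE magnitudes for 166-bit profiles (tens of bits, with a random
reference "above 80") are consistent with the ones-term variant, which is
why both modes are first-class; the binary mode is the default because it
is the classical entropy of the bit distribution. Both satisfy the only
self-contained calibration available: a Bernoulli(0.5) reference scores
above 80 bits in either mode (about 166 and 83 respectively).

Structurally homogeneous libraries polarise probabilities toward 0/1 and
drive SE down while mean pairwise Tanimoto similarity rises; the package's
synthetic library ladder (below) reproduces this inverse relationship
directionally, which is the property the tests assert — not any particular
SE value for a real database, since those depend on proprietary
collections.

**Differential Shannon entropy.** For two libraries $a, b$ the per-bit DSE
is $H(p^{pool}_i) - \tfrac{1}{2}(H(p^a_i) + H(p^b_i))$ with the pooled
probability formed from summed counts. With equal library sizes the pooled
value is the plain average and concavity of $H$ makes DSE $\ge 0$; bits
distributed alike score 0, and a bit always set in one library and never
in the other attains the maximum of 1. When sizes differ under
`weighting = "equal"`, the larger profile is subsampled to the smaller
size by a seeded per-bit hypergeometric draw — the exact marginal law of
subsampling molecules, sufficient because DSE is a per-bit functional.
The size-weighted pooling (no subsampling) is the default.

## Comparing libraries

Between DFPs the package computes city-block distance (on binary vectors,
the Hamming distance; always an integer in $[0, L]$ with zero diagonal) and
$1 -$ Tanimoto. Within a library it computes the exact mean pairwise
Tanimoto for up to `max_exact_n` molecules (default 3000, i.e. ~4.5M
pairs via bit-count linear algebra) and switches to uniform seeded
sampling of distinct pairs beyond that — the application-scale libraries
this method targets reach 25,000+ molecules (~$3\times 10^8$ pairs), where
exact enumeration buys nothing statistically. The `sampled` flag and seed
are recorded in the returned summary. `tanimoto(0-vector, 0-vector)` is
defined as 0, matching the dominant fingerprint-toolkit convention and
avoiding spurious perfect similarity; the choice is logged once per
session.

The linear-cost DFP approximation of intra-set similarity — the mean
Tanimoto between each molecule and the library's own DFP — moves together
with the quadratic-cost pairwise mean across the synthetic ladder (rank
correlation 1 in the tests). On real data the two scales are known to
differ by a roughly constant offset; no direction of that offset is
asserted here, because the published evidence is internally inconsistent
(the prose and the printed table disagree) and the underlying databases
are not available.

## Significant-bit selection and clustering

The procedure originally used for selecting "informationally significant"
bit positions lives in an external package whose algorithm is not
documented; three explicit rules are therefore provided, each fully
specified by quantities this package computes:

* `union_of_dfps` (default) — keep bits set in at least one library's DFP
  at the given threshold. This is the only rule fully determined by stated
  quantities, and its selection count is provably non-increasing in the
  threshold.
* `pooled_entropy_cutoff` — keep bits whose size-weighted pooled binary
  entropy reaches a cutoff.
* `dse_cutoff` — keep bits whose maximum pairwise DSE over library pairs
  reaches a cutoff. Whether the original procedure used pairwise,
  pooled-union or reference-set DSE is unknown; all three behaviours are
  reachable through these rules and none is claimed to be *the* original.

`summarize_libraries()` places each library on the
(mean per-bit SE, mean molecule-vs-DFP Tanimoto) plane, optionally
restricted to a bit selection (which changes the columns analysed, never
the molecule count), and `kmeans_libraries()` groups the points with
seeded multi-restart Lloyd k-means (`stats::kmeans`, Euclidean distance,
default $k = 5$, 10 restarts, 300 iteration cap). Both axes are z-scored
by default so the entropy axis (bits) and the similarity axis (unitless,
$[0,1]$) weigh equally; the reference clustering configuration in the
literature came from an external tool whose initialisation is unstated, so
determinism-by-seed was chosen over any attempt at bit-compatibility.

```{r ladder}
ladder <- make_library_ladder(4, n = 300, seed = 1)
summary <- summarize_libraries(ladder, dfp_threshold = 0.5)
summary
kmeans_libraries(summary, k = 2, seed = 7)
```

## What the synthetic generators emulate — and what they do not

No public fixture can stand in for the proprietary screening collections
this method was demonstrated on, so the package generates its own study
populations:

* `generate_random_reference()` — independent Bernoulli($p$) bits; the
  $p = 0.5$, $1500 \times 166$ default is the random reference condition.
  A seeded Mersenne-Twister stream replaces the atmospheric-noise source
  used historically, which cannot be reproduced deterministically.
* `generate_library()` — independent bits with an arbitrary target
  profile, plus optional correlated blocks: each molecule draws one shared
  latent uniform per block, each block bit uses it with probability
  $\sqrt{\rho}$ and a private uniform otherwise, then thresholds at its
  own $p_i$. Marginals are preserved exactly and any two same-$p$ block
  bits have Pearson correlation $\rho$. This emulates the co-occurrence
  structure scaffold-sharing molecules induce on dictionary keys; it does
  **not** mimic the actual MACCS bit marginals of drugs, GRAS compounds or
  natural products, key-definition dependencies between substructure
  patterns, or molecule-level size effects. Passing tests on these inputs
  therefore demonstrate correctness of the computations and the
  qualitative SE/similarity geometry, not quantitative agreement with any
  real database.
* `make_library_ladder()` — libraries with per-bit probabilities drawn
  uniformly from $[0.5-d, 0.5+d]$, $d$ rising from 0 to 0.4 (500
  molecules per rung by default). Level 1 equals the random reference
  distributionally; homogeneity rises monotonically with $d$, giving the
  controlled diversity spread used by the trend tests.

## Numerical choices and problem sizes

Entropy uses $0\log_2 0 := 0$ and log base 2 throughout. Exact pairwise
means use `tcrossprod` on integer matrices, so they are identical to the
naive per-position loop (asserted on 1000 seeded pairs). Pair sampling
decodes uniform pair ranks to index pairs in double precision, valid past
$2^{31}$ pairs. The `mean_plus_sd` threshold clips at $1 - \epsilon$.
DFP construction at threshold $t$ recovers the generating indicator
$[p^*_i > t]$ from $n = 5000$ molecules whenever $|p^*_i - t| \ge 0.05$ —
by Hoeffding, each bit fails with probability $\le 2e^{-2 \cdot 5000
\cdot 0.05^2} \approx 3\times10^{-11}$ — and the tests check $\ge 99\%$
of bits over replicates. Test problem sizes (libraries of 100–1500
molecules, ladders of 3–4 rungs at 200–500 molecules) were chosen as the
smallest at which the binomial noise bounds above make the asserted
inequalities near-certain rather than borderline.

## Limitations

* Acceptance-grade quantitative checks exist only for the self-contained
  random-reference calibrations (mean pairwise Tanimoto $\approx 1/3$,
  total SE above 80); per-database SE and distance tables from the
  literature depend on unavailable collections and are out of reach.
* PubChem fingerprints are ingested from precomputed FPS/CSV files only;
  generating them from structures requires the external bit-definition
  specification and is out of scope. MACCS generation is delegated to
  OpenBabel when present, with parse failures skipped and warned about.
* Only binary fingerprints are supported — no count-based aggregation, no
  Dice/cosine/Tversky coefficients, and no 2D embedding of the distance
  matrices beyond tidy/ggplot output.
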