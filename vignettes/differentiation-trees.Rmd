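---
title: "Differentiation trees from cell-lineage data: models, statistics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiation trees from cell-lineage data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difftree)
```

## The model

Early mosaic embryogenesis is a rooted, planar, ordered binary tree: the
zygote (depth 0) divides, its daughters divide, and every cell's fate is
fixed by its position in the tree. Two orderings of the same topology carry
different information:

* the **lineage tree** orders each sibling pair by anatomy (e.g. anterior
  left), as published lineage charts do;
* the **differentiation tree** orders each pair by size — smaller daughter
  left, larger right — on the premise that a size-asymmetric division marks
  a differentiation event (the smaller daughter corresponding to a one-cell
  contraction wave, the larger to an expansion wave).

Because only the left/right order changes, the two trees are graph
isomorphic; everything this package computes is a function of that ordering
difference plus the per-cell volume and timing annotations.

Under either ordering, the path from the root addresses each depth-`d` cell
with a bit string `b₁…b_d` (0 left, 1 right). For one cell the lineage code
and the differentiation code have equal length, so their Hamming distance
`D_H` (count of differing bits) is well defined and bounded by the depth.
A single swapped division flips exactly one bit position for every cell in
that division's subtree and nothing outside it — `D_H` localizes ordering
disagreement to sublineages, which is what the isometric-graph view
(`isometric_coordinates()`) displays depth by depth.

## Asymmetry scoring: why the default statistic is `A`, not the printed `G`

A division with daughter volumes `C_i, C_j` is scored by

```
A = |C_i − C_j| / (C_i + C_j),   0 ≤ A < 1,
```

and called asymmetric at confidence threshold `h` when `A > h` (strictly).
`A` is symmetric, scale invariant (units cancel, so relative *Ciona*-style
fractions and absolute *C. elegans*-style µm³ behave identically), and in
exact correspondence with the size ratio `r = C_S/C_L` via
`A = (1 − r)/(1 + r)`.

The confidence-interval formula is sometimes printed with an extra factor,
`G = (|C_i − C_j| / (2(C_i + C_j)))·h`, tested as `G > h`. Taken literally
that form is self-defeating: `|C_i − C_j| < C_i + C_j` for positive
volumes, so `G < h/2 < h` always and *no* division could ever be called
asymmetric — yet the published threshold tables for these data report, for
example, 23 of 117 divisions above `h = 0.50`. Calibrating against those
tables forces the interpretation above: the quantity compared with `h` is
the relative volume difference itself. The package therefore defaults to
`variant = "relative"`, and keeps `"halved"` (`A/2`) and the literal
`"printed"` form available in `asymmetry_statistic()` so the consequences
of each reading can be checked directly.

Boundary convention: `A = h` yields `g = 0` (strict inequality). Divisions
with a missing daughter volume are excluded from the statistics (and
counted in a warning), not imputed.

## Ordering, ties, and overrides

`order_differentiation()` sorts each sibling pair ascending by volume.
Pairs are *tied* when `A ≤ eps`; the default `eps = 0` ties only exact
equality, but `eps` can be set to propagate the confidence criterion into
the ordering itself (treating any division the criterion cannot call as
unordered). Tied or volume-less pairs keep their lineage order and the
mother is recorded in `tree$tie_flags`; the alternative `tie_policy =
"name"` sorts tied pairs alphabetically for deterministic output across
input row orders. The default keeps the published order because early
divisions in real embryos have ratios very close to one, and silently
re-sorting them would manufacture ordering signal out of measurement noise.

`apply_ordering_overrides()` builds the *composite* ordering: named
divisions take an externally supplied order (cell-polarity knowledge at the
two- and four-cell stages, where nucleus-derived volumes are least
trustworthy), all others keep volume order.

## Isometric coordinates

Cells at depth `m` are placed on the line `x + y = N_m − 1` with `x = n`,
the cell's 0-based left-to-right position at that depth under the chosen
reference ordering. `N_m` is the number of cells the tree actually has at
depth `m` — not `2^m` — so incomplete trees (terminal cells, pruned
lineages) are handled without padding. This single concrete map realizes
the "rotated tree" picture however the rotation is described (root at
`(0,0)`; a complete 32-cell layer crosses both axes at 31). Hamming
distances are binned for display as 0, 1–3, 4–6, 7+ by default
(`hamming_bin()`, edges configurable).

The null model (`random_code_null()`) re-orders every division uniformly at
random, under which a depth-`d` cell's `D_H` is Binomial(`d`, ½); observed
per-subtree uniformity against that null is the "biological signal" the
isometric view is meant to expose.

## CAST encoding and alignment

Differentiation codes are serialized as `D.letters` tokens (`C` = 0,
`E` = 1; bits `0,1,0` → `3.CEC`) and two trees' token sequences aligned with
a Needleman–Wunsch dynamic program over whole tokens: +1 per identical
token pair, −1 per gap, substitutions disallowed by default (a configurable
penalty exists for future weighted scoring). The alignment unit is the
whole cell token, because an unmatched code is meaningful as a cell unique
to one differentiation tree; letter-level alignment is deliberately out of
scope.

Sequences are canonicalized (depth ascending, then letters as a binary
value) before alignment unless `canonicalize = FALSE`; `cast_parse()` can
keep a file's native token order so scores computed under a different
serialization convention can be reproduced. For canonical inputs with
substitutions disallowed the optimal score has the closed form
`matches − gaps` with `matches` the multiset intersection size — the test
suite uses that closed form, plus an exhaustive brute-force aligner on tiny
cases, as independent oracles for the DP. Traceback ties are broken
match > gap-in-first > gap-in-second so the aligned output is
deterministic; the score itself is tie-invariant. Truncating both inputs to
depth ≤ 3 (`cast_truncate()`) compares only founder-cell-level structure,
which is the sensible resolution when one tree is a regulative embryo's
tissue tree rather than a cell tree.

## Scaling fits

`fit_power()` fits `y = m·xᵇ` by OLS of `log y` on `log x`: `b` and `R²`
are base-invariant, `m = exp(intercept)`. Noise on lifetimes is modelled
(and simulated) as multiplicative lognormal, which makes the log-scale
regression exactly the generating model, so noiseless data recover
`R² = 1` to machine precision and the parameter-recovery tests have a clean
target. Slope p-values use the usual t distribution on `n − 2` df; the
source analyses report only thresholds ("p < 0.001"), so exact p-values are
not a comparison surface. `outlier_flags()` flags residuals beyond 2.5 SD
(configurable), with a floating-point floor so that an essentially perfect
fit flags nothing.

## What the simulator states, and what a green test establishes

`simulate_tree()` generates a complete binary tree to `max_depth` with root
volume 1 at time 0. Its defaults are the stated world of the test suite:

| parameter | default | why |
|---|---|---|
| `max_depth` | 9 | ~10 division events: the depth range of the real pre-hatch / pre-gastrulation trees |
| split (asymmetric regime) | `0.5·Beta(2, 2)` | broad asymmetries, smaller fraction mean 0.25 |
| split (near-symmetric regime) | `min(u, 1−u)`, `u ~ Beta(200, 200)` | ratios ≈ 0.95, matching the near-unity early-division ratios; `Inf` degenerates to exactly 0.5 |
| `asym_fraction` | 0.2 | sporadic strong asymmetries on a near-symmetric background |
| `asym_onset_depth` | 3 | virtually no size asymmetry before the 8-cell stage |
| `lifetime_coeff` | 10 min | unit-volume (one-cell) lifetime on the scale of early cleavage cycles |
| `lifetime_exponent` | −0.8 | smaller cells live longer; the exponent the recovery tests assert within ±0.1 |
| `lifetime_noise_cv` | 0.1 | multiplicative lognormal, mean 1 |
| `conserve_volume` | TRUE | daughters partition the mother exactly; `FALSE` adds 5% CV lognormal measurement noise, emulating nucleus-derived volumes that do not conserve volume |

The smaller daughter's left/right position in the emitted *lineage* order
is a fair coin, so lineage and differentiation orderings genuinely differ
and the Hamming machinery is exercised nontrivially.

What the simulator does **not** emulate: incomplete/eutelic topologies
(every simulated tree is complete to `max_depth`; per-branch stopping is
out of scope), spatial positions, depth-*dependent* split laws (with
`conserve_volume` the per-depth mean size ratio is stationary — a
deliberate contrast fixture for the depth-varying empirical pattern), and
cross-species topology differences (complete trees contain every binary
code, so two simulated trees of equal depth CAST-align perfectly). A green
test on simulated data therefore establishes correctness of the
computations and the stated statistical behaviour, not biological fidelity
of any particular embryo.

## Numerical and degenerate-input conventions

* Exactly one root; internal nodes have exactly two children (a single
  recorded child is an error, pointing at the missing sibling).
* `volume ≥ 0`; `division_time ≥ birth_time`; a child's `birth_time`
  differing from its mother's `division_time` is a warning (measurement
  noise), not an error.
* Daughter-volume conservation is checked at 10% relative tolerance and
  reported as a warning only — nucleus-derived volumes are not expected to
  conserve volume.
* Both-zero daughter volumes make the asymmetry statistic undefined
  (error); a zero-volume single daughter gives `A = 1`'s limit only
  asymptotically, never exactly.
* Newick export annotates labels with `[&volume=...,t_birth=...,t_div=...]`
  comments; `strip_newick_annotations()` prepares the string for parsers
  that reject comments.

## Known limitations

* The three printed-number acceptance checks (threshold-table counts and
  cross-species CAST scores) need the original deposited workbooks, which
  cannot be shipped with the package; the tests document the expected
  plain-text conversion and fail with instructions when the files are
  absent.
* Nucleus-to-cell volume rescaling for GFP-nucleus datasets is not
  implemented: all shipped statistics are ratio-based and unit-agnostic,
  and no defensible rescaling exponent is available to hard-code. Users
  with a calibrated nucleus-to-cell power law should transform the volume
  column before building the tree.
* No XLSX reader: the pre-installed stack used for this build has none, and
  the workbook layouts vary; convert sheets to the standard CSV dialect (or
  `D.LETTERS` token files for CAST codes) instead.
* Plotting is intentionally absent; all exports are tidy coordinate/record
  tables ready for any plotting layer.
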