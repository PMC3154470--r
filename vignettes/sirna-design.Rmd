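---
title: "Predicting siRNA efficacy and designing mismatched siRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting siRNA efficacy and designing mismatched siRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadesign)
```

## The problem and the model

Knockdown efficacy of an siRNA — the normalized inhibition of its target
transcript, treated throughout as a dimensionless fraction, typically in
[0, 1] but not constrained to it — is determined in large part by the guide
(antisense) strand's own sequence: base composition and, more strongly,
which base sits at which position influence strand selection and RISC
loading. `sirnadesign` models this with an epsilon support-vector regression
(RBF kernel) over fixed-length sequence encodings, and then exploits a
second observation: because RISC loading depends on the duplex and not on
the target, deliberately mutating a guide strand can raise its intrinsic
efficacy, at the price of siRNA:target mismatches whose cost is position-
and identity-dependent. The net score of a mutant is its **mismatch
efficacy**,

$$\mathrm{ME} = E_\mathrm{pred} - \sum_i \Delta E(\text{mismatch}_i),$$

where $E_\mathrm{pred}$ is the SVR prediction for the mutant sequence as if
fully complementary and each $\Delta E$ is read from a penalty table.

Positions are always 1-based, 5′→3′ on the antisense strand; antisense
position $i$ pairs with target position $L+1-i$. Only the four Watson–Crick
pairs count as matches: the G:U wobble is deliberately scored as a
(cheap) mismatch, because mismatch-tolerance measurements treat it as one
and assign it a small but nonzero cost.

## Sequence encodings

All encoders accept DNA or RNA input (T is mapped to U) and reject anything
else. Composition encoders return fractions that sum to 1; positional
encoders return one-hot blocks. On 21-nt input the dimensions are:

| encoder | dimension | notes |
|---|---|---|
| `mono`/`di`/`tri`/`tetra` | 4/16/64/256 | overlapping k-mer fractions, lexicographic A<C<G<U |
| `split_mono`/`split_di`/`split_tri` | 8/32/128 | two halves encoded separately |
| `gapped_di_o`, `gapped_tri_o` | 16, 64 | bases at positions $(i, i+o, \dots)$ |
| `binary` | 84 | one-hot per position |
| `binary_di` | 320 | one-hot dinucleotide per position |
| `condensed` | 40 | mirrored one-hots summed |
| `au_gc` | 42 | weak/strong pair class per position |
| `hbond` | 21 | 2 (A/U) or 3 (G/C) hydrogen bonds |
| `thermo` | 19 | nearest-neighbor stacking energies |
| `accessibility` | 1 | appended scalar |

Three of these required a concrete reading of an ambiguous convention, and
the package fixes them as follows:

* **Split halves.** An odd-length sequence splits into halves that share the
  middle base (a 21-mer into positions 1–11 and 11–21); even lengths split
  exactly. This is the only split that doubles the mono-composition of a
  21-mer to dimension 8 with "nearly half" 11-nt parts.
* **Gapped ("higher-order") composition.** Order $o$ means tuple positions
  $(i, i+o, i+2o, \dots)$; second-order dinucleotides pair base $i$ with
  base $i+2$, so one gap separates the two. The same rule extends to
  triplets.
* **Condensed encoding.** The sequence is folded like a hairpin so the 5′
  and 3′ ends coincide; mirrored positions' one-hot blocks are summed
  elementwise and the odd middle base is dropped — the only simple merge
  that gives dimension $4\lfloor L/2\rfloor$ (40 for a 21-mer).
* **Thermodynamic profile.** The nearest-neighbor table is configuration,
  not code: a standard RNA Watson–Crick $\Delta G_{37}$ stacking set (in
  kcal/mol) ships as `inst/extdata/nn_dg37.tsv` and any complete 16-entry
  table can be substituted. The 19 values of a 21-mer are taken at
  dinucleotide steps 1..19; which 19 of the 20 steps the original
  formulation used is not documented anywhere we could find, so the
  leading-19 choice is our documented convention.

## Scaling and the regressor

Hybrid feature vectors mix fractions (≤1), indicators (0/1), hydrogen-bond
counts (2–3) and energies (negative, magnitude ~3), so each column is
linearly rescaled to [1, 10] using the **training** rows' min and max —
the scaling convention of the libSVM toolchain. Held-out rows are mapped
with the training parameters and *not* clipped, so out-of-range values
extrapolate linearly; constant training columns map to the lower bound.
Scaler fitting happens inside each training fold of cross-validation, so no
information leaks from held-out rows.

Hyperparameters are the triple (`g`, `c`, `j`): `g` is the RBF kernel width
(gamma), `c` the cost. `j` is kept for provenance with SVM-light-style
configurations but has no exact analog in libsvm regression; the package
maps it to the epsilon tube width as `j/100` (default `j = 1` → epsilon
0.01) and documents this as a caveat — users tuning against an SVM-light
reference should treat `j` as approximate. Defaults `g = 0.001, c = 2,
j = 1` are the published hybrid-model settings. Training is deterministic:
refitting, or permuting the training rows, changes predictions only at
numerical precision. Degenerate input with all-equal efficacies draws a
warning and yields the constant predictor (the exact SVR solution in that
case). Predictions are **not** clipped to [0, 1]; published mutant designs
include predicted efficacies slightly above 1 and measured ones below 0,
and clipping would silently distort ME arithmetic.

Cross-validation uses a uniform random fold assignment from a required seed
(default 42); every record is tested exactly once. The headline metrics
(Pearson R, $R^2 = 1 - SS_{res}/SS_{tot}$ — which can be negative — MAE,
RMSE) are pooled over the concatenated held-out predictions, with per-fold
values also reported, since fold-averaged and pooled correlations can
differ and the pooled number is the more conservative, better-determined
one.

## Penalty tables and the ME rules

A penalty table holds single-mismatch entries keyed by (position 1–19,
siRNA base, target base), optional double entries keyed by the unordered
position pair plus both identities, and per-position averages (derived from
the singles, overridable from a second TSV). Lookup applies, in order: the
exact single entry; the exact double entry; otherwise the sum of position
averages — always for ≥3 mismatches, where experimental coverage does not
exist. Each lookup returns a provenance table naming the rule fired for
every mismatch, so a design report can distinguish measured from
extrapolated costs.

The real measured penalties are not publicly printed. The package therefore
ships `generate_synthetic_penalties()`, a clearly labelled stand-in built
from the published positional tolerance tiers: 0.08 efficacy units at the
well-tolerated positions 1, 2, 18, 19; 0.55 at the silencing-critical
positions 5–11; 0.25 elsewhere; identities A:C, G:U and U:G (siRNA:target)
discounted ×0.4 and the poorly tolerated A:G inflated ×1.25, with a seeded
±10% jitter to keep entries distinct. The one published value — U:G at
position 1 costs 0.066 — is pinned exactly. These constants are arguments,
not magic numbers, and any conclusions about *specific* mutants require a
real measured table loaded via `read_penalty_table()`.

Double-depth design re-predicts $E_\mathrm{pred}$ for every double mutant
from its own sequence rather than reusing the single-mutant value; the
single-mutant prediction has no privileged status once a second base
changes. Ranking sorts by ME (descending by default; ascending designs
deliberately weak siRNAs, e.g. against an off-target) with ties broken by
enumeration order — position ascending, then replacement base A<C<G<U — so
the ranking is a total order and reruns are bit-identical.

## Target-site accessibility

The probability that a 16-nt stretch of the mRNA around the target site is
unpaired is an optional scalar feature (`accessibility` encoder). Folding
is delegated to a pluggable backend — a live RNAplfold run (window
`W = 80` nt, max pair span `L = 40` nt, stretch `u = 16` nt, the parameter
set established for discriminating functional siRNAs), a precomputed
RNAplfold `_lunp` profile, or a constant for injection in tests. The u-mer
is anchored at the **3′ end of the target site** (RNAplfold rows index
stretch end positions), a convention this package fixes and documents since
the original description does not say which stretch within the 19-nt site
is used. There is no silent default: a model trained with the accessibility
feature refuses to predict without a backend. The siRNA-submission
workflow (`cmd_mutate`) deliberately omits accessibility, matching the
design it mirrors.

## The synthetic data generator

`generate_synthetic()` draws i.i.d. uniform sequences and assigns
efficacies from a planted linear model over the mono-composition and
positional one-hot features, $y = w^\top x + 0.5 + \varepsilon$, with
weights $w \sim N(0, 0.05^2)$ and noise $\varepsilon \sim N(0, 0.05^2)$.
These defaults make positional effects dominate composition (as in real
screens), give an efficacy spread (sd ≈ 0.2) comparable to published
screens, and set a noise floor low enough that a working SVR must recover
the signal: the packaged recovery experiment (n = 1000, five-fold CV,
seed fixed) attains pooled R ≈ 0.95, and the suite asserts R ≥ 0.85.
A deliberately easier-than-life construction: real efficacy is nonlinear in
sequence, heteroscedastic, and includes target-side effects the generator
omits (no accessibility dependence, no off-target structure, uniform base
usage). Passing the recovery tests therefore validates the *pipeline* —
encoders, scaling, leak-free CV, metrics — not the biological accuracy of
any particular trained model; reproducing published correlations requires
the original training screens, which are external data loaded through
`read_sirna_table()`.

Test and acceptance problem sizes were chosen once: n = 1000 for the
headline recovery experiment, n = 300 for the noise-monotonicity check
(sd ∈ {0.02, 0.1, 0.3}), n = 120 for the shared fixture model. The whole
suite runs in well under a minute on one CPU.

## Known limitations

* The shipped penalty table is a tiered heuristic, not measurement; ME
  values computed from it are for method development only.
* The `j` → epsilon mapping is a documented approximation of a foreign
  toolchain's parameter.
* Mismatch positions are limited to 1–19; 21-nt guides must be designed on
  their 19-nt core.
* No off-target transcriptome search: ranking mutants by ME says nothing
  about where else a mutated seed region may bind.
* Accessibility is a single scalar per site, not a per-position profile,
  and depends on an external folding engine.
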