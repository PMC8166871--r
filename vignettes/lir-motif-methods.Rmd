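---
title: "Scoring LIR motifs and calling mutation-driven gains and losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring LIR motifs and calling mutation-driven gains and losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lirmotif)
library(dplyr)
```

## The problem

Selective autophagy receptors and many other proteins dock onto Atg8-family
proteins (LC3s, GABARAPs) through a short linear motif, the LC3-interacting
region (LIR). The canonical form is the tetrapeptide `[FWY]XX[LIV]`: an
aromatic anchor, two spacer residues, and an aliphatic anchor, usually set in
an acidic context. Because the motif is short, a single missense mutation can
destroy a functional LIR — or create one where none existed. This package
scores candidate motifs, trains the scorer on a benchmark of known motifs,
and tests whether a missense variant significantly shifts a protein's
predicted LC3-binding potential.

## The scoring model

A candidate site is represented by an 18-residue window: the 4-residue core
plus 7 flanking residues on each side. Windows that run off a terminus are
padded with `*`, which is a first-class character of the 24-letter scoring
alphabet (20 amino acids plus `B`, `Z`, `X`, `*`), so every window is scored
without special cases.

The raw score of a query window $P$ against the $N$ reference (positive)
windows $K_1 \dots K_N$ is the average position-weighted substitution
similarity

$$
S \;=\; \frac{1}{N}\sum_{j=1}^{18}\Big(\sum_{i=1}^{N} M[P_j, K_{ij}]\Big)\,W_j ,
$$

with $M$ a symmetric substitution matrix over the 24-letter alphabet (300
unique entries) and $W$ a vector of 18 non-negative position weights. Before
training, $M$ is BLOSUM62 and all $W_j = 1$. Scoring is vectorized through
the reference residue-count matrix, so a batch of windows costs 18 table
lookups per window regardless of $N$.

When a reference window is itself scored (during cross-validation or
calibration), it is excluded from the reference set by its
(accession, core start) identity — the leave-one-out convention used
throughout.

## Training

Model quality is measured by the leave-one-out AUC over a benchmark of
positive windows (annotated motifs, canonical and atypical alike) and
negative windows (every other canonical-regex core in the same proteins,
minus any candidate whose 4-residue span overlaps an annotated core). The
optimizer is a stochastic hill climb with two phases run to convergence and
alternated until a full pass accepts nothing:

* **PWD** (position weight determination) proposes changes to one of the 18
  weights;
* **SMO** (scoring matrix optimization) proposes changes to one of the 300
  unique matrix entries.

Each step either perturbs one randomly chosen parameter by $\pm 1$ (random
mutation, probability 0.9) or sets it to exactly zero (random zeroing,
probability 0.1); the proposal is kept only if the LOO AUC strictly
increases. The strict inequality guarantees termination; the zeroing moves
act as a structural L1 device that prunes uninformative parameters, and an
explicit L1 penalty subtracted from the objective is available through
`lambda` (default 0, since no penalty weight is prescribed for this
optimizer). Weights are constrained to be non-negative — a negative position
weight would reward dissimilarity — while matrix entries are free. A phase
ends after `stop_patience` consecutive rejections (default 1000; the
examples and the acceptance script use 150–300, which on benchmarks of
~130 positives and ~700 negatives converges in a couple of minutes while
leaving the AUC within noise of longer runs).

Because acceptance requires a strict AUC increase, the training trajectory
is non-decreasing by construction, and identical seeds reproduce identical
models bit for bit.

## From scores to posteriors

Raw scores are calibrated to Bayesian posterior probabilities:

$$
p(P \mid S) \;=\;
\frac{f(S \mid P)\, p(P)}{f(S \mid P)\, p(P) + f(S \mid N)\, p(N)},
$$

where $f(S\mid P)$ and $f(S\mid N)$ are one-dimensional Gaussian kernel
densities fitted to the min–max-scaled positive (leave-one-out) and negative
benchmark scores, $p(P)$ is the model's LOO AUC and $p(N) = 1$. The
class-conditional bandwidths are chosen by the same maximum-likelihood grid
search used for the pair density below (its one-dimensional analog). Scores
outside the calibration range are clipped to it. One consequence worth
knowing: far above the calibration range the posterior saturates, so a large
raw-score drop between two saturated windows can translate into a small
posterior displacement.

## The pair density and conditional significance

For a missense variant, every core whose 18-residue window covers the
variant position — whether the core exists in the original sequence, the
mutant, or both — yields a pair $(x, y)$: the posterior of the original
window and of the mutant window. The joint distribution of pairs over a
mutation corpus is modelled with a two-dimensional Parzen window:

$$
f(x,y) \;=\; \frac{1}{n h^2}\sum_{i=1}^{n}\frac{1}{2\pi}
\exp\!\Big[-\tfrac{(x-x_i)^2 + (y-y_i)^2}{2h^2}\Big].
$$

The bandwidth $h$ is selected on the grid $0.0001, 0.0002, \dots, 1$ by
maximizing the leave-one-out likelihood $\prod_i f_{-i}(x_i, y_i)$. The
log-likelihood is smooth in $h$, so the implementation refines the grid in
three stages (steps 0.01, 0.001, 0.0001 around the running argmax); the
exhaustive scan is retained as an option and the test suite asserts that
both return the same grid point. For large corpora the likelihood is
evaluated on a seeded uniform subsample (`kde_subsample`, default 20,000
pairs) — the argmax is stable under subsampling long before that size.

Significance of a mutation is assessed conditionally: for the observed $x$,
the conditional density $f(y \mid x)$ is renormalized over $[0,1]$ on a
0.001 grid (trapezoidal integration), and the p-value is the upper tail
$P(Y \ge y \mid x)$ when $y > x$ (candidate gain) or the lower tail
$P(Y \le y \mid x)$ when $y < x$ (candidate loss). A pair with $y = x$
(possible after clipping) is assigned $p = 1$. Calls are then gated twice:
**Type I** (gain) requires $y > x$, $y > 0.5$ and $p < 0.01$; **Type II**
(loss) requires $x > y$, $x > 0.5$ and $p < 0.01$. Both thresholds are
configurable (`lir_config`).

The power of this test depends on the corpus composition, not only on the
planted effect: the conditional tail at a given $x$ is essentially the local
fraction of strongly displaced pairs. A corpus in which displaced pairs are
common at some score level cannot call any of them significant there —
exactly the behaviour one wants from a rarity test.

## Term enrichment

Called proteins can be tested for annotation enrichment with the exact
hypergeometric upper tail: with $N$ the annotated universe, $n$ a term's
membership, $M$ the query inside the universe and $m$ the overlap, the
enrichment ratio is $(m/M)/(n/N)$ and a p-value is reported only when it
exceeds 1, as the upper tail $\sum_{m' \ge m}$. Benjamini–Hochberg
correction is optional and off by default, matching the raw-threshold
reporting conventional for this analysis.

## The synthetic study conditions

All tests run against a seeded generator, so no external data is needed.
Its defaults define the study conditions and deliberately mirror the shape
of a real benchmark and mutation corpus:

* 127 positive motifs planted in 105 proteins of length 400; negatives are
  the chance regex matches in the same proteins (~650–900 of them, set by
  the background composition, not tuned).
* Positive windows are drawn from a per-position emission model: aromatic
  anchor `W/F/Y` at 0.5/0.3/0.2, aliphatic anchor `L/I/V` at 0.4/0.3/0.3,
  inner flanks (offsets −4…−1, +1, +2) enriched for `D/E/S/T` (0.15 each),
  all other positions at background. A `signal_strength` parameter
  interpolates towards background; anchors interpolate within their residue
  class so positives always match the regex.
* The background is a proteome-like residue composition rather than a
  uniform one. This matters more than it may seem: with a uniform
  background, chance cores carry anchors as aromatic-rich as true motifs,
  the anchor positions lose almost all label signal, and the optimizer can
  legitimately zero the anchor weight — after which anchor-destroying
  mutations are invisible to the caller. Real proteomes make tryptophan
  rare, anchors discriminative, and anchor weights worth keeping; the
  generator emulates that. A uniform background remains available
  (`aa_background("uniform")`) for analytically simple nulls.
* The variant generator plants 10 anchor-destroying losses and 6
  anchor-creating gains on *prototypical* windows (aromatic anchor `W`, at
  least 3 of the 6 enriched flank offsets in `D/E/S/T`) — the synthetic
  analog of staging validated exemplars on strong motifs — against 6000
  neutral variants: 85% at the non-informative outer window offsets of
  existing cores (half on annotated motifs, half on chance cores) and 15%
  outside every candidate window. Weak-effect near-diagonal pairs therefore
  dominate the pair density at every score level, as they do in a real
  corpus where called gains and losses are a fraction of a percent of all
  candidate mutations.

What passing these conditions does and does not show: recovery of planted
events demonstrates that the scoring, calibration, density and calling
machinery compose correctly under a motif structure the model can represent.
It does not certify performance on real motifs, whose flanking preferences,
disorder context and benchmark curation noise the emission model does not
attempt to reproduce.

## Numerical choices and edge cases

* AUC uses the rank-statistic (Mann–Whitney) formulation with ties counted
  ½, making it a proper probability and the complement identity
  `auc(s) + auc(-s) = 1` exact for tie-free scores.
* Zero denominators in the six threshold metrics yield `NA`, never an error.
* Bandwidth likelihoods are computed in log space with a per-row
  log-sum-exp guard, so coincident points select the smallest grid value
  instead of overflowing.
* The conditional integral is restricted to $[0,1]$ (posteriors live
  there); kernels are not truncated — normalization happens in the
  conditional denominator. A query $x$ with vanishing conditional mass is
  an error in the scalar API and an `NA`/`none` row in batch calling.
* Terminal `*` padding is scored through the matrix like any residue; no
  position masking.
* Model JSON stores the 300 unique matrix entries keyed by character pair
  and numbers at full precision, so save/load round-trips are bit-exact and
  two runs with the same seed produce byte-identical files.

## Problem sizes

The worked examples, tests and the acceptance script use the generator
defaults above: a 127/~700 benchmark, training patience 150–300, and a call
set of roughly 7,000 candidate rows whose pair-density bandwidth is selected
on a 3,000-pair subsample. These sizes keep a full pipeline run in the
low minutes on a single CPU while leaving every estimate far from its
small-sample regime.

## Known limitations

* The additive scorer cannot express hard residue requirements; a window
  with excellent flanks but a destroyed anchor may keep a moderate score.
  Posterior saturation (see above) can further mute such losses at the very
  top of the score range.
* The LOO-AUC objective rewards separating positives from regex-matching
  negatives; features shared by both classes (e.g. the anchor classes
  themselves under unrealistic backgrounds) receive little weight.
* The conditional test is one-sided by the sign of $y - x$; a two-sided
  variant would halve the nominal level but not change the machinery.
* Atypical (non-regex) motifs enter the reference set through annotations
  but are never produced by proteome scanning, which enumerates canonical
  cores only.
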