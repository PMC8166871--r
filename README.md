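# lirmotif

Selective autophagy runs on a short linear motif: the LC3-interacting region
(LIR, also called the Atg8-interaction motif), canonically the tetrapeptide
`[FWY]XX[LIV]` set in an acidic context. Because the motif is four residues
long, a single missense mutation can abolish a functional LIR or create one
from a near-miss — with direct consequences for how a protein engages the
autophagy machinery. `lirmotif` is for computational biologists who want to
(i) score candidate LIR motifs in protein sequences, (ii) train the scorer
on a benchmark of known motifs, and (iii) call missense variants that
significantly **gain** (Type I) or **lose** (Type II) predicted LC3-binding
potential.

## The method in brief

A candidate site is an 18-residue window (core ± 7 flanking residues,
`*`-padded at termini). Its raw score against the *N* reference motifs
*K₁…K_N* is the average position-weighted substitution similarity

S = (1/N) Σⱼ ( Σᵢ M[Pⱼ, K_ij] ) · Wⱼ,  j = 1…18,

with M a symmetric substitution matrix over a 24-letter alphabet (300 unique
entries; BLOSUM62 before training) and W ≥ 0 a vector of 18 position
weights (all 1 before training). Training is a seeded stochastic hill climb
on the leave-one-out AUC: alternating phases over the weights and the matrix
entries propose ±1 perturbations or zeroings of single parameters and keep
only strict improvements.

Raw scores are calibrated to Bayesian posterior probabilities
p(P|S) = f(S|P)·p(P) / (f(S|P)·p(P) + f(S|N)·p(N)), with kernel-density
class conditionals, p(P) = the model's LOO AUC and p(N) = 1. For a missense
variant, each affected core yields a pair (x, y) of original/mutant
posteriors; the corpus of pairs is modelled with a 2-D Parzen window
f(x,y) = (1/nh²) Σᵢ (1/2π) exp(−[(x−xᵢ)² + (y−yᵢ)²]/2h²), its bandwidth
chosen by maximum leave-one-out likelihood on a 0.0001-step grid, and each
pair is tested against the conditional tail of y given x. Calls require
p < 0.01 plus a posterior gate: Type I needs y > x and y > 0.5, Type II
needs x > y and x > 0.5. A hypergeometric enrichment test (E-ratio with the
exact upper tail) is included for downstream annotation analysis of called
proteins.

Everything is testable offline: a seeded generator produces proteomes with
planted motifs, benchmark tables, and variant sets with known
gain/loss/neutral truth. See the methods vignette
(`vignettes/lir-motif-methods.Rmd`) for model assumptions, parameter
defaults, and design choices.

## Worked example

```r
library(lirmotif)
library(dplyr)

sim <- generate_benchmark(n_pos = 60, n_proteins = 50,
                          protein_length = 300, seed = 42)
sim
#> <lir_simulation> 50 proteins, 60 positives, 205 negatives, signal = 1

cfg <- lir_config(seed = 42, stop_patience = 100, kde_subsample = 2000)
fit <- train_lir_model(sim$benchmark, cfg)
fit
#> <lir_training> LOO AUC 0.837114 -> 0.982114 over 341 accepted proposals

cal <- calibrate_model(fit$model, sim$benchmark, cfg)
cal
#> <lir_calibration> p(P) = 0.9821 | h_pos = 0.022 h_neg = 0.0406 | raw range [ -42.47 , 18.37 ]

vars <- generate_variants(sim, n_loss = 8, n_gain = 4, n_neutral = 1500,
                          seed = 42) |>
  distinct(accession, position, ref_aa, alt_aa, .keep_all = TRUE)
calls <- call_lams(sim$proteins, vars, fit$model, cal, config = cfg)
count(calls, verdict)
#> # A tibble: 3 × 2
#>   verdict     n
#>   <chr>   <int>
#> 1 TypeI       3
#> 2 TypeII      6
#> 3 none     1557
```

The numbers read as follows: the untrained scorer separates planted motifs
from chance regex matches at LOO AUC 0.837; hill-climb training lifts that
to 0.982, which also becomes the positive prior of the calibration. Of
~1,500 candidate (variant, core) pairs, nine are called — six Type II
(anchor-destroying, e.g. a `W → G` substitution at a planted core with
original posterior x ≈ 0.98 collapsing to y ≈ 0.02 at p ≈ 6e-3) and three
Type I (anchor-creating `P → W` with x ≈ 0 rising to y ≈ 0.9). The `none`
rows are dominated by the planted neutral variants, as they should be.

Single pieces are exposed too:

```r
scan_clir_cores("FAALWAAV")   # core starts: 1 (FAAL) and 5 (WAAV)
#> [1] 1 5
extract_window("WEMV", 1)     # terminal padding
#> [1] "*******WEMV*******"
```

`autoplot()` methods show the trained weight profile, the training
trajectory, and the (x, y) pair density; `plot_lam_calls()` draws the call
scatter; `tidy()`/`glance()` return model parameters and one-row summaries.
A thin command-line wrapper with `simulate` / `train` / `scan` / `evaluate`
/ `call-lams` / `enrich` subcommands lives at `inst/cli/lirmotif.R`.

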