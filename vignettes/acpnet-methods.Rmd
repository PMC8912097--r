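---
title: "Methods: a hybrid sequence/physicochemical classifier for anticancer peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid sequence/physicochemical classifier for anticancer peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpnet)
```

## The problem

Anticancer peptides (ACPs) are short (roughly 10--50 residue) peptides that
kill or inhibit tumor cells, typically through membrane disruption. They are
characteristically cationic (lysine/arginine-rich) and amphipathic, which
makes them partially predictable from sequence alone. Screening candidates
experimentally is slow, so a sequence-based classifier that ranks peptides by
ACP likelihood is a practical triage tool. This package implements such a
classifier: a binary model that scores a peptide in $[0,1]$ and calls it an
ACP when the score strictly exceeds a threshold (0.5 by default).

## The model

The classifier fuses two views of the same peptide:

* **Manual branch (MS).** A 35-dimensional engineered feature vector passed
  through fully connected layers. The features are largely independent
  summaries of composition and physicochemistry, which suits a dense network.
* **Embedding branch (AE).** The raw residue sequence, index-encoded
  (A$\to$1, C$\to$2, ..., Y$\to$20, alphabetical by one-letter code), mapped
  through a learned 21-row embedding table (row 0 is the padding index) and
  read by a bidirectional LSTM. The sequence is treated as a time series;
  the LSTM cell uses the standard forget/input/output gate equations
  $f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)$, etc., with
  $c_t = f_t \circ c_{t-1} + i_t \circ \tanh(W_c x_t + U_c h_{t-1} + b_c)$
  and $h_t = o_t \circ \tanh(c_t)$.

The final hidden states of the two directions are concatenated (the least
lossy way to combine them) and joined with the manual branch output; a dense
head ends in a single sigmoid unit trained with binary cross-entropy — the
natural loss for a probability score thresholded at 0.5. The `mode`
configuration field (`"MS"`, `"AE"`, `"MS+AE"`) switches branches off for
ablation studies without changing feature order or any other contract.

### The 35 manual features

| block | dim | definition |
|---|---|---|
| PAAC | 30 | pseudo amino acid composition, $\lambda = 10$, $w = 0.05$ |
| length | 1 | residue count $L$ |
| Shannon entropy | 1 | $-\sum_i f_i \ln f_i$ over the 20 frequencies |
| GRAVY | 1 | mean Kyte--Doolittle hydropathy |
| molecular weight | 1 | sum of average residue masses + 18.0153 Da water |
| charge at pH 10 | 1 | Henderson--Hasselbalch net charge |

PAAC extends the plain amino-acid composition $f_1..f_{20}$ with $\lambda$
sequence-order correlation factors
$\tau_k = \frac{1}{L-k}\sum_{i=1}^{L-k} J(R_i, R_{i+k})$, where
$J(a,b) = \frac{1}{3}\sum_q [\Phi_q(b) - \Phi_q(a)]^2$ averages squared
differences over three per-residue property scales, and the whole vector is
normalized to sum to one:
$p_u = f_u / (1 + w\sum_k \tau_k)$ for $u \le 20$ and
$p_{20+k} = w\,\tau_k / (1 + w\sum_k \tau_k)$. $\lambda = 10$ requires
$L \ge 11$; shorter sequences are a hard error rather than a silent
$\lambda$ reduction, because the descriptor is undefined there and the
benchmark length regime (minimum 11) makes $\lambda = 10$ always legal.

Design choices that the descriptor definitions leave open, pinned here for
reproducibility:

* **Property scales.** Kyte--Doolittle hydropathy, Hopp--Woods
  hydrophilicity, and the classical side-chain mass table. Each scale is
  standardized to mean 0 and population SD 1 across the 20 residues before
  entering $J$ — the convention of the PAAC literature; without it side-chain
  mass (range $\sim$130) dominates the other two scales. Scales are
  pluggable through `paac_params()`.
* **Entropy log base.** Natural log. The downstream network is invariant to
  the scale, but the choice is pinned so feature files are comparable.
* **Molecular weight.** Average (not monoisotopic) masses, plus one water;
  the convention of standard protein-analysis tools.
* **Charge.** EMBOSS-style pKa values (C 8.5, D 3.9, E 4.1, H 6.5, K 10.8,
  R 12.5, Y 10.1, N-terminus 8.6, C-terminus 3.6), pluggable via
  `charge_params()`. The pH-10 feature separates strongly cationic peptides
  (which stay positive there) from the rest and is qualitatively robust to
  the exact table.

### Encoding, padding, truncation

Index encoding post-pads with the reserved index 0 to `max_len`, which
defaults to the longest training sequence and travels with the trained
model. Padding positions are masked in the recurrent branch: the hidden and
cell state are held unchanged through them, so the forward direction ends at
each sequence's true last residue. The backward direction reads each
sequence's valid prefix reversed (padding stays trailing), so both
directions share one masked implementation. Longer inference sequences are
truncated at `max_len` with a warning.

### Architecture and training defaults

The published description of the architecture this package follows names the
branch types but not the exact layer widths, so the defaults here are
deliberately ordinary small-data settings, every one a configuration knob:
embedding dimension 50; 64 LSTM units per direction; manual branch
64--32; merged head 64--32--1; dropout 0.3 on dense hidden activations
(inverted dropout, training only); Adam at learning rate $10^{-3}$ with the
standard bias correction; batch size 32; up to 200 epochs with early
stopping on validation loss (patience 20, best-epoch weights restored).
Manual features are z-scored with training-set statistics frozen into the
model — molecular weight ($\sim 10^3$) would otherwise swamp the PAAC
components ($\sim 10^{-2}$). The forget-gate bias is initialized to 1, other
weights Glorot-uniform, the padding embedding row to zero.

The whole network, including backpropagation through time, is implemented in
R on BLAS matrix operations. Analytic gradients are verified against central
finite differences to $\sim 10^{-10}$ in the test suite, which is the
strongest single correctness check a hand-built network can carry. Training
is deterministic under `seed` with a single-threaded BLAS; scores are exact
probabilities, and the label rule is the strict inequality
`score > threshold` (a score exactly at the threshold is non-ACP).

## Evaluation

`metrics_from_counts()` implements the standard confusion formulas —
accuracy, F1, recall, precision, and the Matthews correlation coefficient
$\mathrm{MCC} = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP{+}FN)(TP{+}FP)(TN{+}FP)(TN{+}FN)}$.
A zero factor under the MCC root (or an empty precision/recall denominator)
reports 0 with a `degenerate` flag instead of failing, so batch evaluation
survives pathological folds. ROC AUC is trapezoidal over all score
thresholds, equivalent to the rank-average (Mann--Whitney) treatment of
ties; the PR area uses the average-precision step convention, which differs
slightly from trapezoidal PR integration and is therefore documented as
such. Percentages print with one decimal; underlying values stay at full
precision.

The package ships the 20-peptide independent validation fixture (10 proven
ACPs, 10 non-ACPs) with the scores the original classifier printed for
them. The fixture's ground truth follows provenance, not the printed
predictions; the two disagree only on row 8, the single proven ACP scored
below 0.5 (0.4979). Applying the strict `> 0.5` rule to the printed scores
reproduces TP = 9, TN = 10, FP = 0, FN = 1.

## The synthetic benchmark

`generate_peptides()` draws residues i.i.d. from per-class composition
weights, lengths uniform on 11--50 — the short-peptide regime of the public
ACP benchmarks. Positives up-weight K, R, L, W, I, F (cationic/hydrophobic,
the composition visible in known ACPs); negatives up-weight D, E, G, S. The
profile is a qualitative test scaffold, not a fitted biological model. What
it emulates: the compositional signal that separates ACPs from background
peptides, at an effect size a composition-only classifier can learn. What it
does not emulate: positional motifs, amphipathic periodicity, secondary
structure, shared evolutionary ancestry between train and test, or
class-imbalanced screening pools — so a high synthetic accuracy demonstrates
that the pipeline learns and evaluates correctly, not that it will reach the
same accuracy on real peptides. Passing identical weights for both classes
gives a null dataset on which a correct pipeline must sit near chance; the
tests assert both directions.

## Problem sizes and numerical choices

The test suite and the acceptance script train on 200+200/50+50 splits of a
500-peptide synthetic benchmark at up to 40 epochs (patience 8), and a
three-seed ablation comparison at 100+100/30+30 — sizes chosen so the whole
suite runs comfortably on one CPU while still leaving each ablation mode
clear room above the 0.90 accuracy bar. The null-control run uses 15 epochs;
with no signal to find, longer training only oscillates around chance.
Degenerate inputs are errors, not coercions: empty sequences, non-canonical
residues, sequences with $L \le \lambda$, single-class training sets, and
empty validation sets all fail loudly with the offending record named.

## Known limitations

* The headline published test-set numbers (accuracy 89.6%, AUC 0.945 on an
  82+82 benchmark) are not reproducible from this repository alone: they
  require the original benchmark FASTA files and the exact published layer
  sizes, neither of which is distributed here. With those data supplied, a
  retrained model of this architecture is expected to land within a few
  points of the published accuracy over seeds, but that is an informational
  expectation, not a gated result; what is recomputed exactly is every
  metric row from its printed confusion counts.
* Whether the original 80/20 split was stratified is unstated; this package
  stratifies by default, which is conservative for balanced classes.
* The embedding is per-token; positional information enters only through
  the recurrent dynamics.
* Training on CPU in R is practical at benchmark scale (hundreds of
  peptides) but not for large-scale screening; inference is cheap.
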