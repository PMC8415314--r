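---
title: "Calling copy-number variations with an MEA-initialized neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy-number variations with an MEA-initialized neural network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmeann)
```

## The problem and the model

Copy-number variations (CNVs) — duplications or deletions of genomic
segments from about 1 kb to several Mb — are a major class of structural
variation and a recurrent cause of disease.  In short-read sequencing
data the primary CNV signal is read depth (RD): a duplicated segment
attracts proportionally more reads, a deleted one fewer.  In tumor
samples the signal is diluted by normal-cell contamination: at tumor
purity $p$ the expected RD of a segment with tumor copy number $c$ is
proportional to the two-genome mixture

$$\mathrm{RD} \propto (1-p)\cdot 2 + p \cdot c,$$

so a heterozygous deletion at purity 0.3 shifts RD by only 15%, easily
lost in counting noise.  `cnvmeann` therefore classifies genome bins not
on RD alone but on three features jointly:

* **RD** — the number of reads whose leftmost aligned base falls in the
  bin, scaled to reads per kb (a 1 kb bin reports its read count
  directly);
* **GC-content** — the G+C fraction of the bin's reference sequence.
  GC bias is *not* corrected away; it enters as a feature and the
  classifier learns how (and whether) it matters;
* **mapping quality (MQ)** — the mean MAPQ of the bin's reads.  Reads
  that map to several locations get low mapping quality, and CNV-prone,
  repeat-rich regions are exactly the regions where this happens, so MQ
  carries class signal that RD does not.

Each bin $i$ is the triple $B_i = (R_i, G_i, Q_i)$.  All three features
are min–max normalized to $[0,1]$ with extrema taken over **all bins of
all profiles** in the training pool (`fit_minmax()`); calling reuses the
training extrema, clamping unseen values into $[0,1]$.  Training data is
the quadruple $(g, q, r, L)$ with per-bin labels $L \in \{0,1,2,3\}$ for
normal, gain, hemi_loss (one homolog lost) and homo_loss (both lost).

### The classifier

A fully connected feedforward network with 3 input neurons, $h = n + 3m
= 15$ hidden neurons and 4 output neurons (one per state).  The hidden
activation is

$$f(x) = \frac{2}{1+e^{-2x}} - 1,$$

a sigmoid with range $(-1,1)$ — algebraically identical to $\tanh(x)$,
and tested to machine precision against it.  The hidden layer computes
$H_j = f(\sum_i \omega_{ij} b_i - \lambda_j)$; the output layer is
linear, $P_k = \sum_j H_j \omega_{jk} - \eta_k$.  At prediction time the
linear outputs are mapped through the logistic function to $(0,1)$ and
read as per-state probabilities; a bin's label is the argmax, with exact
ties broken toward normal and then toward the lower label index.

### Training

Per-example backpropagation with learning rate $\mu = 0.1$ and one-hot
targets.  The residual is $e_k = E_k - P_k$ on the *linear* outputs, so
the weight updates

$$\omega_{jk} \mathrel{+}= \mu H_j e_k, \qquad
  \omega_{ij} \mathrel{+}= \mu (1 - H_j^2) b_i \textstyle\sum_k \omega_{jk} e_k$$

together with the threshold updates $\lambda_j \mathrel{-}= \mu (1-H_j^2)
\sum_k \omega_{jk} e_k$ and $\eta_k \mathrel{-}= \mu e_k$ are exact
gradient descent on the example's squared error — the test suite checks
the update against a central-finite-difference gradient and verifies
that a small-step update never increases the error.  Two deliberate
numerical choices are worth recording.  First, the hidden-layer factor:
with $H_j \in (-1,1)$, the often-quoted factor $H_j(1-H_j)$ is not the
derivative of $f$ and changes sign for $H_j < 0$, which destroys the
descent guarantee; the default rule uses the true derivative $1-H_j^2$,
and `rule = "as_printed"` in `train_step()`/`nn_train()` provides the
literal textbook recursions (including the unscaled output-threshold
step $\eta \mathrel{+}= e$) for comparison.  Second, training residuals
are measured on the linear outputs rather than the logistic-mapped ones:
with one-hot targets the two agree on the argmax, but the linear form
makes the stopping rule attainable and the updates exactly
gradient-like.

Epochs visit the training rows in a freshly shuffled order; training
stops when every row's maximum absolute output error is at most $e_0$
(default 0.1, never stated with the method's other defaults and exposed
as a parameter) or after `max_epochs` (default 100).  Non-convergence
is reported via a flag, not an error — with noisy bins near the class
boundary the $e_0$ criterion is routinely unattainable and the epoch cap
is the practical stop.

### Mind evolutionary algorithm

Backpropagation from random weights is sensitive to its starting point.
The MEA searches the flat 124-gene vector (105 weights + 19 thresholds,
`encode_params()`/`decode_params()`) before gradient descent starts:

1. **Scoring.**  An individual's score is the reciprocal of the mean
   squared error of its decoded network on the training data,
   $F = N/\sum (E-P)^2$ with $N$ the number of training outputs
   ($4m$); residuals here use the logistic-mapped outputs, keeping the
   score landscape bounded.  A residual sum below $10^{-12}$ caps the
   score at $10^{12}$.
2. **Population.**  200 individuals drawn uniformly in $[-1,1]^{124}$;
   the 5 best seed *superior* subgroups, the next 5 *temporary*
   subgroups; each subgroup is filled to 20 members with Gaussian
   perturbations of its center.
3. **Similartaxis** (local search): each subgroup repeatedly re-samples
   its members around its best individual (sd `similartaxis_sd`,
   default 0.1) until the best has not improved for
   `maturity_patience` (3) consecutive rounds.  The best is always
   retained, so a subgroup's score never decreases.
4. **Dissimilation** (global competition): subgroup scores are posted on
   a bulletin board; any temporary subgroup beating the worst superior
   subgroup replaces it, and the vacated slot is re-seeded with fresh
   random individuals — the escape hatch from local optima.
5. After `max_iterations` (8) outer rounds — or earlier if the bulletin
   best stagnates for `stagnation_patience` (5) rounds — the best
   individual ever seen initializes the network.

The canonical population structure (5 + 5 subgroups of 20 = 200) is
preserved every iteration and the bulletin best is non-decreasing, both
asserted by tests.  Iteration count, maturity rule and perturbation
scale are not fixed by the method's published parameter table; they are
free `mea_config()` choices, and the defaults were sized so that a
training run on a few thousand bins completes in tens of seconds.

### From bins to calls

Maximal runs of consecutive bins sharing a non-normal label are merged
into one call (a state change breaks a run); runs shorter than
`min_bins` are dropped.  `merge_calls()` itself defaults to
`min_bins = 1`, but the pipeline default stored in trained models is 3:
isolated misclassified bins otherwise surface as 1-bin calls, and at
the default 1 kb bin size a 3-bin minimum still reports any CNV of 3 kb
and larger.  Flagged bins (no reads, hence no MQ) are labeled normal and
break runs.

Benchmarking (`evaluate_calls()`): a truth event is *identified* when a
call of the same state overlaps it reciprocally by at least 50% (both
fractions configurable, and `match_state = FALSE` gives the
state-agnostic variant that gain/loss-only callers are scored with).
Sensitivity is identified truth / total truth, precision is matching
calls / total calls, F1 their harmonic mean.  Boundary bias is the mean
over matched pairs of $(|s_{call}-s_{truth}| + |e_{call}-e_{truth}|)/2$
in bp — a summary of breakpoint accuracy whose exact formula is a
package choice.

## The simulator, and what it does (not) show

`simulate_profile()` emulates a tumor sample *at the feature level*: it
does not simulate reads, but draws per-bin (RD, GC, MQ) directly.

* Baseline RD is `coverage_depth * bin_size / read_length` reads per
  bin (60 at 6x, 1 kb bins, 100 bp reads).  Inside events the mean is
  multiplied by $1+p/2$, $1-p/2$ or $1-p$ for gain / hemi_loss /
  homo_loss — the mixture model above with tumor copy numbers 3, 1, 0.
* RD noise is Gaussian with sd `rd_noise_sd * baseline * sqrt(mult)`,
  i.e. variance proportional to the local copy number, as for counts.
  The default CV is 0.05: the simulator models the effective dispersion
  of a processed RD signal, chosen so that the standard purity ladder
  0.2/0.3/0.4 spans hemi-loss shifts of 2–4 noise sd — the regime in
  which published RD callers degrade at low purity and saturate at
  purity 0.4 — rather than the raw per-bin Poisson floor (CV ≈ 0.13 at
  6x/1 kb), under which no per-bin classifier can reach that regime.
* MQ is `mq_baseline` (60) minus `mq_drop_in_cnv` (10) inside events,
  with Gaussian sd 2 — the mappability-loss signature of CNV-prone
  repeat regions.  GC is uniform on `gc_range` and independent of class
  by default; the `gc_bias` hook couples RD to GC for robustness
  experiments.
* Events: `n_events_per_class` per CNV class, lengths uniform on 8–15
  bins, placed non-overlapping with at least one normal bin between
  events; `simulate_study()` crosses purities × coverages × replicates.

Deliberate omissions: no paired-end or split-read information, no SNV
or haplotype structure, no GC-coupled coverage waves, no mappability
track, no real breakpoint microhomology.  A pipeline that is accurate
here has learned to combine an attenuated RD shift with an MQ drop
under Gaussian noise — evidence the architecture and training work, not
a claim about any particular sequencing platform.  `write_sam_fixture()`
bridges toward real inputs by materialising a profile as an actual
FASTA + SAM pair whose extracted features reproduce the planted ones,
which is how the alignment-based feature extractor is tested end to end.

## Feature extraction conventions

* A read is assigned to the bin containing its **leftmost aligned
  base**; RD is that count scaled to reads per kb.  (Whether to count
  by start or by overlap is a convention; counting by start makes RD an
  unbiased per-bin count and is declared, not inferred.)
* Unmapped, secondary, supplementary and duplicate-flagged alignments
  are excluded from both RD and MQ.
* Zero-read bins have undefined MQ: they are flagged (`mq = NA`) and
  excluded from training and calling rather than imputed.
* Bins whose reference sequence is more than 50% N have undefined GC
  and are likewise flagged; GC is computed over non-N bases.
* Coordinates are 0-based half-open everywhere inside the package;
  SAM output is 1-based as the format requires.
* A constant feature (max = min) normalizes to 0 rather than NaN.

## Problem sizes and defaults used in validation

The shipped validation runs train on two simulated 5000-bin samples
(purity 0.4, 6x, 15 events per class, ~1300 training bins after
balancing the normal class down to the CNV classes) and call a third,
held-out sample; with default MEA and training settings this completes
in well under a minute on one core and reaches sensitivity and
precision above 0.95 with sub-bin boundary bias.  The MEA-benefit
comparison trains from MEA and from random initialization over five
seeds on a purity-0.3 sample with a reduced epoch budget (30), where
the starting point still matters; the MEA median F1 is consistently at
least the random-init median.  Class balancing is off by default in
`assemble_training_set()` but on in `run_train()`: with ~10:1
normal:CNV imbalance the squared-error objective otherwise spends most
of its capacity on the easy majority class.

## Known limitations

* Per-bin classification has no spatial smoothing; a single
  misclassified bin splits a long event into two calls.  The 50%
  reciprocal-overlap benchmark is therefore conservative for very long
  events.
* No purity or ploidy estimation: the classifier must be trained at a
  purity regime matching the samples it will call.
* Single-sample calling only; no matched-normal subtraction.
* The $e_0$ stopping rule is global (max over all rows); one hard bin
  keeps training running to the epoch cap.
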