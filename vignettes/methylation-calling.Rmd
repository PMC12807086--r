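---
title: "Calling 5mC from nanopore ionic signals with a small transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 5mC from nanopore ionic signals with a small transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a DNA strand translocates a nanopore, the measured ionic current is
modulated by the handful of bases inside the pore — roughly seven
nucleotides at a time. A 5-methylcytosine carries the same base identity as
an unmethylated C but perturbs the current, and the perturbation bleeds into
the neighboring events because the modified base stays inside the pore
while its neighbors translocate. Methylation calling is therefore a
sequence-context problem: the signal at a CpG only becomes interpretable
relative to what the surrounding k-mers *should* look like unmethylated.

`methformer` implements a compact transformer encoder that classifies the
center event of a window of consecutive, reference-anchored events as
methylated or not, and aggregates per-read calls into genome-scale per-site
methylation frequencies. The package deliberately consumes already-anchored
event tables (read id, chromosome, strand, 0-based reference position,
reference base, raw samples): basecalling, alignment and re-squiggling are
upstream concerns.

## Event features and normalization

Raw currents drift between reads, so each read is normalized on its own:
all samples of the read are pooled, centered by their median and scaled by
1.4826 × MAD, then clipped to [−5, 5]. Median/MAD standardization is used
instead of mean/sd because single-sample current spikes are common and
would otherwise leak into the scale estimate; the clip guarantees the
stated range. A read with zero MAD (constant signal) falls back to scale 1
with a warning. Normalization of already-normalized data is a near no-op
(idempotent up to clipping), which the test suite checks.

Each event then becomes a 7-feature vector
⟨f_m, f_sd, f_l, f_A, f_C, f_G, f_T⟩: the mean and the population standard
deviation of its normalized samples, the number of samples (dwell), and the
one-hot base identity in the fixed order A, C, G, T. Two conventions are
deliberate choices where the convention is genuinely open: the standard
deviation is the population form (ddof 0), and the dwell count is stored
raw.

The raw dwell count is an order of magnitude larger than the other
features, and a layer-normalized encoder computes its statistics across the
row — so dwell fluctuations (pure noise) would modulate the effective scale
of the informative signal features. The model therefore standardizes the
three numeric columns (f_m, f_sd, f_l) at its input, with means and
standard deviations estimated once from the training split and serialized
in the checkpoint; the stored features themselves stay raw, so containers
and file formats are unaffected.

For every candidate CpG (a C immediately followed by G on the same strand;
both-strand scanning returns the palindromic partner position flagged
minus-strand), the classifier input is the window of w = 21 consecutive
events centered on the candidate: ⌊w/2⌋ upstream and ⌊w/2⌋ downstream
events by event order within the read. Candidates closer than ⌊w/2⌋ events
to a read end are skipped rather than padded — padding semantics would
invent signal where none was observed — and the number of skipped
candidates is reported.

## Position embeddings

Self-attention is order-agnostic, so row order must be injected explicitly.
The embedding of position i with width n is sinusoidal: component 2j is
sin(i·w0^(2j/n)) and component 2j+1 is cos(i·w0^(2j/n)), with base
frequency w0 = 1/10000; for odd n the final unpaired component is the sine
term. Positions are window-relative (0 … w−1), never genomic — genomic
coordinates would make the embedding unbounded.

Two attachment strategies are implemented and compared by the ablation
harness:

* **concat** (the default): each 7-feature row gains an n_pe-wide embedding,
  so d_model = n_pe + 7. The small reference model uses n_pe = 9, d_model
  = 16. Note the frequency ladder uses the embedding's own width n_pe in
  the exponent, so the ladder spans exactly the components that exist.
* **sum**: elementwise addition requires matching widths, so the 7-feature
  row is first mapped through a learned affine projection to d_model; the
  projection is trained jointly with the encoder.

The evenness constraint is enforced on d_model (which also must be a
multiple of the attention-head count), not on n_pe — the 9 + 7 = 16
configuration is legal by construction.

## The encoder-classifier

The model is a standard pre-norm transformer encoder: n_layers = 2 layers,
each holding a multi-head self-attention sub-layer (n_heads = 2) and a
position-wise feed-forward sub-layer (d_ff = 4·d_model, ReLU), each wrapped
in a residual connection with layer normalization; a final layer norm
closes the stack. Pre-norm ordering is chosen for training stability at
this tiny scale. The classification head reads the encoder output at the
center row only — the label belongs to the center event, and center-slicing
(rather than pooling) keeps the correspondence exact — and applies
FC(d_model→d_model) → ReLU → FC(d_model→2) → softmax. A read-level call is
methylated iff the methylation probability strictly exceeds 0.5; ties go to
unmethylated.

Dropout 0.1 is applied to both sub-layer outputs during training only;
evaluation is deterministic, and checkpoints reload bit-exactly.

Because no tensor/autograd framework is involved, forward and backward
passes are explicit base-R matrix code. The analytic gradients are verified
against central finite differences in the test suite, along with two
structural probes: with the embedding block zeroed, the output is exactly
invariant to permutations of the non-center window rows (attention without
positions cannot see order), and the parameter count matches a closed-form
function of (d_model, n_heads, n_layers, d_ff).

## Training

The loss is two-class cross-entropy, minimized with Adam (β₁ = 0.9,
β₂ = 0.98, the transformer-customary second-moment horizon) under gradient
clipping at global L2 norm 1 — a saturated softmax can emit a single huge
gradient that would otherwise poison the moment estimates. The peak
learning rate follows a linear warmup over the first 10% of steps and a
cosine decay to 10% of the peak; for short runs (tens of epochs) flat Adam
at an aggressive rate is noisy at the end and timid at the start, and the
schedule removes much of that seed-to-seed variance. Batches are reshuffled
each epoch under the training seed, and the checkpoint with the best
validation F1 is kept. Tunable scopes follow the model's hyperparameter
table: batch size 256–512 (default 256), peak learning rate 0.001–0.01.
With a 10-epoch budget on thousands of windows, held-out F1 typically lands
between 0.95 and 0.99 but individual seeds can fall a few points short —
the optimization, not the signal, is the binding constraint at this model
size.

**The validation split is grouped by genomic site.** All windows whose
center is the same (chrom, position, strand) land on the same side of the
split. A window-level split would leak: the 21 one-hot rows fingerprint a
site almost uniquely, and labels are site-linked, so a model can score
validation windows by memorizing training sites — inflating metrics even
when no methylation signal exists. The site-grouped split is the
within-simulation analogue of training on one genome and evaluating on
another, and it is what makes the package's delta = 0 null control
meaningful: training on data simulated with no methylation shift yields
held-out AUC ≈ 0.5, confirming the pipeline has no leakage path.

Metrics are computed from the confusion counts (accuracy, precision,
recall, F1) plus ROC AUC via the Mann–Whitney pairwise-concordance formula
with ties counted 0.5. Ratios with zero denominators are reported as 0 and
flagged `undefined` rather than returned as NaN, keeping reports
machine-readable. All metric code is cross-checked in the tests against
brute-force reimplementations and, for AUC, against pROC.

## The simulator

The simulator provides the controlled truth the real data cannot: every
quantity the pipeline is supposed to recover is planted explicitly.

* **Reference and reads.** A uniform-random ACGT genome (CpGs arise
  naturally, about one per 16 bp); reads are random substrings emitted as
  consecutive events, forward-strand by default (minus-strand reads behind
  a flag carry reverse-complement bases and levels).
* **Level map.** Each event's clean level is a deterministic, seeded
  function of the k-mer centered on its base (k = 7), with N(0,
  level_scale²) marginals. The map is the sum of position-additive base
  effects and a per-k-mer idiosyncratic deviation, with the deviation
  carrying fraction `kmer_frac` = 0.5 of the standard deviation. The split
  matters: real pore models are largely additive in base composition —
  which is precisely why a caller trained on one genome can work on
  another — but not perfectly so. A purely iid-random map would make
  context correction unlearnable for held-out sites (nothing would
  generalize); a purely additive map would be unrealistically easy. The
  exported map makes runs auditable: the same k-mer always yields the same
  clean level.
* **Methylation.** Each CpG site is methylated with probability 0.5; each
  read agrees with its site's status with probability
  `read_meth_fidelity` (default 1). In a methylated read copy, the
  `shift_span` = 7 events around the C gain `delta` times a triangular
  taper (weight 1 at the center, falling linearly to the edges) — the
  in-pore footprint expressed in event space.
* **Noise and dwell.** Samples per event are 1 + Poisson(dwell_mean − 1)
  with dwell_mean = 8; each sample adds N(0, noise_sd²) noise, noise_sd =
  0.3. Signals are emitted on an arbitrary raw scale (offset 100, scale 10,
  picoampere-like) so the pipeline's per-read normalization is genuinely
  exercised.

What the simulator does *not* emulate: stay/skip events and signal drift,
alignment indels (windows are event-indexed, and simulated reads are
gapless), chemistry-specific k-mer tables, and sequence-composition bias.
Passing the recovery studies therefore demonstrates that the architecture,
gradients, training loop and aggregation are correct and that the method
can exploit exactly the signal structure it assumes — not that any given
accuracy will transfer to real flowcell data.

## Reference study conditions

The acceptance studies (also re-run by `scripts/acceptance.R`) use:

* **Recovery study:** 6 kb genome, 440 reads × 300 events (~22× coverage,
  ~8000 CpG windows), delta = 2.0, noise_sd = 0.3; d_model = 16, 2 heads,
  2 layers, window 21, concatenated embeddings; batch 256, peak learning
  rate 0.01 (the top of the tuning scope, appropriate for a 10-epoch
  budget), 10 epochs, 25% of sites held out. Expected outcome: held-out F1
  ≥ 0.95 and AUC ≥ 0.98; site-status accuracy ≥ 0.95 and mean |frequency −
  ρ| ≤ 0.1 at coverage ≥ 20. Coverage ~22 is chosen so the site-level
  check has sites above its coverage floor.
* **Null control:** 24 kb genome, 240 reads × 400 events (~4× coverage),
  delta = 0, 30% of sites held out. Because predictions at a site are
  nearly identical across reads (the level map is shared), the effective
  sample size of the AUC is the number of validation *sites*, not windows;
  the null study is therefore sized wide and shallow (~450 validation
  sites) so chance-level AUC is estimated tightly.
* **Ablations:** one small dataset (2.5 kb, 120 reads × 250 events)
  extracted once at window 31 and centrally cropped per run, so every
  window size scores the identical candidate set; embedding modes
  {sum, concat} × 3 seeds and window sizes {11, 21, 31}.

Site-level frequency error is reported as the mean absolute deviation over
sites. Per-read errors at a site are strongly correlated (all reads share
the site's k-mer levels), so occasional fully-miscalled sites are the
expected failure mode of *any* caller on this data; a per-site worst-case
bound would be unattainable in principle, while the mean couples directly
to site-status accuracy.

## Known limitations

* Windows are indexed by event order, not genomic distance; real aligned
  reads with indels would shift context slightly.
* The head reads only the center row; pooling variants are not explored.
* Training is single-threaded R matrix code — comfortable for the reference
  model sizes (thousands of windows, d_model 16–64), not for flowcell-scale
  data.
* The simulator's Gaussian, drift-free signal model understates the tails
  of real current noise.
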