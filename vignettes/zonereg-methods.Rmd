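---
title: "Models and methods behind zonereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zonereg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Hepatocytes change state along the portocentral axis of the liver lobule
(zonation). The working model this package implements is that zonated
enhancer activity is written in the DNA sequence as a *core hepatocyte code*
-- binding sites for HNF4A, HNF1A, CEBPA, FOXA1, ONECUT1 and NFIB-class
factors shared by all hepatocytes -- mixed with binding sites for two zonated
repressors: a TBX3-class motif associated with periportal accessibility and a
TCF7L1/2-class motif associated with pericentral accessibility. Loss of a
repressor site de-represses the enhancer in the corresponding zone; gain of a
core site raises activity. `zonereg` provides a self-contained, desk-scale
computational stack for studying this model: a generative motif-grammar
simulator with known ground truth, a convolutional sequence classifier with
transfer learning, sequence interpretation tools, reporter-assay (MPRA)
activity calling, in-silico network perturbation, and pseudotime-to-spatial
mapping onto a virtual lobule.

Everything is testable end to end because every input is simulated with known
ground truth. The package does not download or require any external dataset.

# The synthetic motif grammar

`make_default_grammar()` fixes the study conditions for all synthetic
experiments:

* **Sequences** are 500 bp (configurable), i.i.d. background at GC fraction
  0.41 (a typical mammalian regulatory-region composition).
* **Motifs** are consensus-dominated PWMs. The HNF4A-like motif is exactly
  `CAAAGTCA`; the TCF7L1-like and TBX3-like repressors are 11-bp PWMs whose
  cores are `GATCAAAG` and `AGGTGTGA`. The TCF7L1/HNF4A pair deliberately
  shares a `CAAAG` core -- the two motifs overlap in real hepatocyte
  enhancers, and this overlap is what makes zonation a non-trivial sequence
  problem. Repressor PWMs carry flanks around the printed 8-mer cores because
  the 8-mers are the *cores* of wider binding models: a naked 8-mer in 500 bp
  of background is matched near-perfectly by chance often enough that the
  zonation classes stop being identifiable even to an oracle scan with the
  true PWMs.
* **Sharpness.** Each PWM column gives probability 0.92 to its consensus base
  (plus a small seed-controlled jitter, U(0, 0.008), so columns are not all
  identical). This was calibrated once, against two generator guarantees the
  package promises its downstream modules: (i) an oracle log-odds scan with
  the true PWMs separates the three zonation classes with AUROC at or above
  0.95, and (ii) planted instances of the wide (>= 11 bp) patterns are
  recoverable at 90% within +/- 2 bp with at most 10% false loci. At 0.85
  dominance neither guarantee holds -- sampled instances carry too many
  mismatches relative to what a 500-bp background produces by chance.
* **Copy numbers.** Core motifs: 2-3 motif types per sequence, 1-3 copies
  each. Repressors: exactly 2 copies (one copy is missed too often by any
  detector when the insertion strand is random). Insertion positions are
  uniform over valid offsets, strands uniform, overlaps re-drawn up to 100
  times and then an error.

Label schemes: `zonation` (general = core only; pericentral = core +
TCF7L1-like; periportal = core + TBX3-like), `activity` (active = at least
two core insertions, inactive = none, decoys only), and `topic` (the three
hepatocyte classes plus two decoy cell-type classes, emitted multi-label).

What the generator does *not* emulate: real genome composition and repeats,
positional preference or spacing grammar between sites, cooperative/soft
syntax, read-level noise. A model passing these tests has learned motif
occupancy logic under ideal labels; that is the intended scope, not evidence
about real chromatin.

# The sequence classifier

The classifier maps one-hot DNA (channels A, C, G, T; `N` encodes as zeros)
to class scores:

* convolution with `n_filters` position weight filters of width
  `filter_len`, ReLU;
* **strand-invariant global max pooling**: the convolution and pooling run on
  the sequence and its reverse complement and the pooled feature is the
  elementwise maximum over both orientations, so a motif instance scores the
  same on either strand;
* a dense ReLU layer (`dense_units`) with inverted dropout during training;
* a sigmoid head for multi-label topic classification (a region may belong to
  several topics), or a softmax head for one-of-k zonation / activity
  classes.

Filters can be initialised from PWMs: each PWM is log-odds transformed
(`log2(p/0.25)`, clipped to [-3, 3]), centred and zero-padded into one
filter; remaining filters are random. Optimisation is Adam at `lr_base`
(1e-3) with an internal 10% validation split for early stopping; the weights
of the best epoch (minimum validation loss, accuracy tiebreak) are kept and
the full history (loss, accuracy, AUPR per epoch) is retained on the model.
All randomness flows from the configuration seed, so training is exactly
reproducible.

Design choices made where the design was genuinely open:

* *No recurrent layer.* A recurrent layer over pooled convolution maps is a
  plausible architecture for long-range syntax, but the grammar this package
  targets is an occupancy code: what matters is which motifs occur (on either
  strand, in either copy), not their order. Global max pooling over both
  orientations is the minimal architecture that represents exactly that, it
  is robust to train at desk scale, and it keeps every gradient (including
  gradients with respect to the input, used for attribution) exact and fast
  in plain matrix algebra.
* *Strand handling in the architecture* rather than by data augmentation:
  augmenting with reverse complements doubles training cost and still leaves
  test-time predictions strand-sensitive; max-pooling over orientations makes
  the invariance structural.
* *Transfer learning.* All layers initialise from the base model except a
  fresh output head. The transferred layers fine-tune at `lr_transfer`
  (1e-5); the fresh head trains at `lr_base`, because a randomly initialised
  head cannot move away from its initialisation at 1e-5 within any desk-scale
  epoch budget. The provenance chain (base model id) is recorded on the model
  and survives serialisation.
* *Cross-validation* splits by parent region, so sliding-window augmented
  copies of one region never span training and evaluation, and test
  evaluation uses the non-augmented centre windows. Ten groups rotate: one
  test, the next validation, eight training.

Default sizes in `model_config()` follow the headline architecture
(1,024 filters of width 24) where stated; the examples, tests and the
acceptance script use a scaled-down configuration (24 filters of width 12,
dense 32) which the synthetic grammar is fully learnable by -- problem sizes
were chosen so the whole stack trains in minutes on one CPU core.

# Interpretation

* `contribution_scores()` implements expected gradients (integrated
  gradients averaged over baseline sequences, a DeepSHAP-class estimator).
  The contract is local accuracy: contributions sum to
  `f(x) - mean f(baselines)` up to path-integration error; the test suite
  checks it within 5% on a trained network and exactly on a linear scorer.
  The returned map is the importance matrix multiplied by the one-hot
  sequence, so rows are zero off the reference base; the unmasked importance
  matrix is kept alongside because local accuracy holds only for the full
  attribution. Attribution targets the post-activation class score by
  default (`target = "logit"` is available).
* `saturation_mutagenesis()` scores all 3L single-nucleotide variants in one
  deterministic batch; entries at reference bases are exactly zero. On
  synthetic zonated sequences the most negative delta for the zone class
  falls inside the planted repressor instance in over 80% of test sequences.
  Mutagenesis and attribution agree where importance lies; the agreement is
  measured as linear (Pearson) correlation of per-position magnitudes,
  because at desk scale most positions are background whose near-zero scores
  carry independent noise in the two maps and dilute a rank correlation
  computed over all positions.
* `trim_by_ic()` trims PWM flanks whose information content (bits, uniform
  background) falls below a fraction (default 0.25) of the PWM's maximum
  column IC; interior low-IC columns are kept; a fully uninformative PWM is
  an error.
* `scan_instances()` calls motif instances by cross-correlating the trimmed
  log-odds filter with the one-hot sequence on both strands (activation
  mode), or by summing contribution-map entries under the pattern window
  (contribution mode). Activation thresholds are deliberately explicit
  configuration with no hidden defaults. The package's documented operating
  point for the default grammar is `max attainable score - 12` (roughly a
  two-mismatch budget), at which planted instances of the >= 11 bp patterns
  are recovered at >= 90% within +/- 2 bp with <= 10% false loci. Shorter
  degenerate motifs (the 8-9 bp core motifs) cannot be called at locus level
  at any threshold in this background -- an information-content limit of the
  motifs themselves, not of the scanner.
* `design_variant()` edits sequences: gain-of-function replaces a locus with
  the pattern consensus; loss-of-function mutates the k (default 3)
  highest-IC positions to the column's least likely base. Edits are minimal
  and recorded. Destroying the planted periportal repressor site in a
  periportal sequence raises the model's pericentral score, mirroring the
  de-repression logic of the underlying biology.

# MPRA activity calling

Counts are normalised by plain median-of-ratios size factors (pseudo
reference = per-enhancer geometric mean across samples; enhancers with any
zero count are excluded from factor estimation), and
`logFC = mean log2(normalised cDNA + 0.5) - mean log2(normalised plasmid + 0.5)`.
This plain estimator deliberately stands in for a shrinkage-based package so
the computation is self-contained; correctness is established by synthetic
calibration (the estimator is unbiased as dispersion vanishes) rather than by
numeric parity with any external tool. The null model is a Gaussian fitted to
the shuffled-control log fold changes -- robustly by default
(median location, normal-consistent scaled MAD) -- giving one-sided
upper-tail p-values (activity is enrichment over plasmid; the choice of
sidedness is this package's, made explicit here). Benjamini-Hochberg runs
over non-control enhancers only and an enhancer is active when its adjusted
p is strictly below alpha (default 0.1). Under the pure-null generator the
empirical FDR stays at or below alpha; enhancers with true activity of
2 log2 units at the default depth (1e6) and dispersion (0.1) are recovered
with power above 0.9.

Barcode assignment collapses raw (barcode, enhancer) observations, filters
against an explicit IUPAC template (such as the degenerate design
`NNNYRNNNYRNNNYRNNN`), and flags barcodes seen with more than one enhancer;
only unique barcodes count. FACS-fraction analyses reuse the bulk plasmid
samples as the denominator, mirroring designs where sorted fractions have no
plasmid libraries of their own.

The count simulator uses a negative binomial parameterised by
(mean, dispersion) with variance `mean + dispersion * mean^2`; per-sample
expected totals equal the requested depth, and shuffled controls draw their
abundances from the same distribution as real enhancers so their plasmid
marginals match.

# GRN perturbation

`fit_target_models()` fits one regressor per target gene (gradient-boosted
trees, 500 rounds, depth 3, learning rate 0.05; a linear mode exists to
enable exact analytic checks -- rank-deficient designs drop collinear columns
as zero effects). `simulate_perturbation()` clamps the chosen TF (0 for
knockdown; the maximum over the selected cells for overexpression), then
re-predicts every target and re-clamps over `n_iter` iterations (default 5;
the underlying procedure prescribes only "several") so indirect effects
propagate; the mean absolute update per iteration is reported as a
convergence trace. Fold changes use a 0.01 pseudocount on the expression
scale. On the default mutual-repression network, knocking down the
periportal repressor raises the pericentral repressor and its activated
targets, overexpression reverses every sign, and the embedding arrows
(`embedding_shift()`: each perturbed profile placed at the distance-weighted
mean coordinate of its k = 10 nearest original cells in a 50-component PCA
feature space -- the projection method is this package's choice) move
repressor-high cells toward the opposite zonation pole.

# Virtual lobule and zonation testing

`simulate_lobule()` generates the spatial template parametrically (uniform
samples in a hexagonal disc, central-vein cells at the centre, portal
structures at the six vertices) rather than segmenting a drawing; each
zonated virtual cell carries its normalised radial distance and an
equal-frequency distance bin. `map_cells()` assigns real profiles to virtual
cells bin by bin: sampling without repetition when real cells outnumber
virtual ones, balanced floor/ceiling multiplicities otherwise; non-zonated
types are sampled at the type level without binning. `fit_zonation()` tests
features along pseudotime with a natural cubic spline (df = 5) on the
pseudotime rank scale against an intercept-only null (F-test,
Benjamini-Hochberg, significant below adjusted p 0.01 by default). The
spline-on-ranks choice stands in for an unspecified GAM basis/family; it is
Gaussian on whatever (ideally log-normalised) values are supplied, and rank
fitting makes the test invariant to monotone relabelling of pseudotime.
When several modalities are tested (genes, regions), adjust each separately
by calling `fit_zonation()` per modality. Pseudotime direction is the
caller's responsibility: bins are oriented by the supplied pseudotime, and
portal-versus-central anchoring must be fixed upstream (the simulator's
pseudotime runs portal to central).

# Numerical and degenerate-input conventions

* Coordinates are BED-style 0-based half-open everywhere, including motif
  instances within sequences.
* Rank ties (peak scores, pseudotime bins, top-n label cutoffs) break by
  stable deterministic order; cutoff ties in topic label selection warn.
* Regions at the contig start are shifted inward so windows keep exact width.
* Equal-frequency bins differ in size by at most one.
* All generators are pure functions of (parameters, seed); model training is
  reproducible from the configuration seed; model bundles reload bit-exactly
  from disk (`save_model()` / `load_model()`).

# Known limitations

* The simulator's ideal labels overstate what any model could achieve on
  real single-cell data; reported AUROCs characterise the implementation,
  not the biology.
* Instance calling is information-limited for short degenerate motifs (see
  above); sum-score reporting is raw (no cross-width normalisation), with
  the pattern width carried in each record.
* The logFC estimator carries no dispersion shrinkage; at very low counts
  its variance is larger than a shrinkage estimator's would be.
* The GBM perturbation model cannot extrapolate beyond the observed
  expression range; overexpression clamps are therefore taken from observed
  maxima, never synthetic values.
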