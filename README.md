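# zonereg

Enhancer grammar, reporter activity and spatial zonation analysis for the
liver lobule — a self-contained, desk-scale R package.

## The scientific problem

Hepatocytes change state continuously along the portocentral axis of the
liver lobule ("zonation"). A working model of how this is encoded in DNA is
that zonated enhancers carry a shared *core hepatocyte code* (binding sites
for HNF4A-, HNF1A-, CEBPA-, FOXA1-, ONECUT1- and NFIB-class factors) plus
sites for zone-restricted factors — a TCF7L1/TCF7L2-class input at the
pericentral pole and a TBX3-class input at the periportal pole — with the two
zonated factors mutually repressing each other's program. Testing analysis
code for this model on real data is slow and ground truth is unknowable, so
`zonereg` pairs every analysis step with a generator that plants the grammar
into synthetic sequences, counts and cells with exact ground truth.

The package covers the full loop:

1. **Synthetic ground truth** — a motif grammar (`make_default_grammar()`)
   and simulators for labelled enhancer sequences
   (`simulate_labeled_sequences()`), MPRA count tables
   (`simulate_mpra_counts()`), zonated single-cell expression driven by a
   small enhancer-GRN (`simulate_zonated_expression()`), and a virtual
   lobule template (`simulate_lobule()`).
2. **Regions and I/O** — iterative consensus-peak merging
   (`iterative_peak_merge()`), window augmentation (`augment_windows()`),
   FASTA/BED6/TSV round-trips.
3. **Sequence classifier** — a convolutional network written against base R
   and BLAS: PWM-initialised convolution, strand-invariant max pooling, a
   dense ReLU layer with dropout, and task-specific heads; trained with Adam
   and early stopping (`train_base()`), with transfer learning onto related
   labellings (`train_transfer()`), grouped cross-validation
   (`cross_validate()`) and exact save/load round-trips.
4. **Interpretation** — expected-gradients attribution
   (`contribution_scores()`), in-silico saturation mutagenesis
   (`saturation_mutagenesis()`), information-content motif trimming
   (`trim_by_ic()`), motif-instance scanning (`scan_instances()`) and
   gain/loss-of-function variant design (`design_variant()`).
5. **MPRA processing** — barcode assignment, oligo assembly, median-of-ratios
   normalisation with log2 fold changes (`compute_logfc()`), and activity
   calling against a robust Gaussian null fitted on shuffled controls with BH
   correction (`call_active()`).
6. **GRN perturbation** — per-target regressors (`fit_target_models()`,
   gradient-boosted trees or linear), iterated clamped knockdown /
   overexpression (`simulate_perturbation()`) and embedding-shift arrows
   (`embedding_shift()`).
7. **Pseudotime-to-space mapping** — rank-binned pseudotime
   (`bin_pseudotime()`), bin-matched assignment of real cells onto the
   virtual lobule (`map_cells()`), profile transfer (`transfer_profiles()`)
   and a spline test for zonated features (`fit_zonation()`).

Everything returns tibbles or small S3 objects with `tidy()` / `glance()` /
`autoplot()` methods.

## Worked example

The script below is runnable as-is; the output shown is what it actually
printed.

```r
library(zonereg)

## 1. Simulate a labelled enhancer compendium from the motif grammar
grammar <- make_default_grammar(seed = 1)
sim <- simulate_labeled_sequences(grammar, n_per_class = 250, "zonation",
                                  seed = 42)
sim$set
#> <seq_set> 750 sequences of length 500-500 bp; classes (onehot): general, pericentral, periportal
head(sim$ground_truth, 3)
#> # A tibble: 3 × 6
#>   seq_id      class   motif   start   end strand
#>   <chr>       <chr>   <chr>   <int> <int> <chr>
#> 1 general_001 general Onecut1   183   192 +
#> 2 general_001 general Hnf4a     393   401 +
#> 3 general_001 general Hnf4a      52    60 -

## 2. Train a compact classifier and evaluate on held-out sequences
cfg <- model_config(n_filters = 24L, filter_len = 12L, dense_units = 32L,
                    dropout = 0.2, max_epochs = 24L, early_stop_patience = 6L,
                    batch_size = 64L, seed = 1L)
idx <- withr::with_seed(1, sample(length(sim$set)))
model <- train_base(sim$set[idx[1:600]], cfg, pwms = grammar$motifs$pwm)
evaluate(model, sim$set[idx[601:750]])
#> # A tibble: 3 × 5
#>   class       auroc  aupr n_pos n_neg
#>   <chr>       <dbl> <dbl> <int> <int>
#> 1 general     0.941 0.904    60    90
#> 2 pericentral 0.959 0.923    44   106
#> 3 periportal  0.992 0.984    46   104

## 3. Locate the base whose mutation most damages the pericentral score
i <- idx[601:750][which(sim$set$labels[idx[601:750], "pericentral"] == 1)[1]]
mm <- saturation_mutagenesis(model, sim$set$sequences[i], "pericentral")
worst <- which(mm$delta == min(mm$delta), arr.ind = TRUE)[1, "row"] - 1L
gt <- sim$ground_truth
site <- gt[gt$seq_id == sim$set$ids[i] & gt$motif == "Tcf7l1", c("start", "end")]
cat(sprintf("most damaging position: %d; planted Tcf7l1 sites: %s\n",
            worst, paste(sprintf("[%d, %d)", site$start, site$end),
                         collapse = " ")))
#> most damaging position: 265; planted Tcf7l1 sites: [265, 276) [41, 52)

## 4. MPRA activity calling against shuffled controls
mpra <- simulate_mpra_counts(c(rep(0, 300), rep(2, 40)), n_shuffled = 100,
                             seed = 7)
calls <- call_active(compute_logfc(mpra$table), alpha = 0.1)
glance(calls)
#> # A tibble: 1 × 7
#>   n_enhancers n_controls n_active frac_active null_location null_scale alpha
#>         <int>      <int>    <int>       <dbl>         <dbl>      <dbl> <dbl>
#> 1         340        100       46       0.135       -0.0786      0.330   0.1

## 5. In-silico TF perturbation on the zonation eGRN
egrn <- make_default_egrn()
expr <- simulate_zonated_expression(egrn, 200, noise_sd = 0.05, seed = 3)
fit <- fit_target_models(expr$expr, egrn, seed = 1)
kd <- simulate_perturbation(fit, expr$expr, "Tbx3", "KD", n_iter = 3)
kd
#> <perturbation_result> Tbx3 KD, 3 iterations; mean |update| per iteration: 0.432, 0.304, 0
head(dplyr::arrange(tidy(kd), dplyr::desc(fc)), 4)
#> # A tibble: 4 × 4
#>   gene        fc mean_perturbed mean_original
#>   <chr>    <dbl>          <dbl>         <dbl>
#> 1 Tcf7l1    1.79           2.16          1.20
#> 2 PCgene07  1.59           3.64          2.29
#> 3 PCgene02  1.59           3.20          2.01
#> 4 PCgene06  1.55           2.41          1.56

## 6. Map pseudotime-binned cells onto a virtual lobule
tpl <- simulate_lobule(400, c(hepatocyte = 1.0), seed = 5)
real <- tibble::tibble(cell_id = sprintf("hep_%03d", 1:600),
                       cell_type = "hepatocyte", bin = rep_len(1:10, 600))
asg <- map_cells(tpl, real, seed = 6)
feature <- withr::with_seed(8, real$bin + rnorm(600, 0, 0.5))
vals <- matrix(feature, ncol = 1, dimnames = list(real$cell_id, "zoned"))
mapped <- transfer_profiles(asg, vals)[tpl$virtual_id, ]
cat(sprintf("virtual cells: %d; |cor(mapped feature, radial distance)| = %.3f\n",
            nrow(asg), abs(cor(mapped, tpl$radial_dist))))
#> virtual cells: 400; |cor(mapped feature, radial distance)| = 0.950
```

Knocking down the periportal repressor Tbx3 de-represses the pericentral
factor Tcf7l1 (fold change 1.79) and its activated targets — the expected
sign structure of the mutual-repression circuit — and the mapped zonated
feature reproduces the portocentral gradient on the virtual lobule.

## Command-line interface

A thin wrapper over the same functions ships in `inst/cli/zonereg.R`
(requires `optparse`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "zonereg.R", package = "zonereg"))')" \
  merge --peaks a.bed,b.bed --out merged.bed
```

Subcommands: `merge` (consensus-peak merging), `augment` (window
augmentation), `logfc` (MPRA normalisation), `call` (activity calling),
`lobule` (virtual-lobule mapping). All inputs and outputs are plain
TSV/BED6 text files; run any subcommand with `--help` for its options.

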