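# replicall

Replicate-based consensus calling and benchmarking of somatic SNVs.

## The problem

Somatic single-nucleotide variants (SNVs) are called by comparing tumor and
matched-normal sequencing from the same patient. At exome scale the calls are
noisy: the same mapper-and-caller pipeline applied to independently prepared
*biological replicates* of one tumor/normal pair produces visibly different
call sets, and different callers disagree even more. Because somatic calls
drive diagnosis and targeted therapy, this irreproducibility matters.

`replicall` implements and evaluates the replicate-consensus remedy: treat
each replicate's call set as a vote and keep the variants detected in at
least *m* of *n* replicates of the **same** pipeline,

```
keep v  <=>  |{ i : v in callset_i }| >= m ,  1 <= m <= n .
```

`m = 1` is the union, `m = n` the intersection. Raising `m` trades recall for
precision; in multi-center replicate studies of the SEQC2 tumor/normal
benchmark (HCC1395, truth set of 1,159 high-confidence exome SNVs) the best
F1 is obtained with majority voting — "detected in at least two of three
replicates" — within a sequencing center. Scoring follows the standard
confusion metrics against the truth set inside evaluable regions:

```
precision = TP/(TP+FP)    recall = TP/(TP+FN)    F1 = 2PR/(P+R) = 2TP/(2TP+FP+FN)
```

The package also tests the downstream use of consensus sets: training a
variant classifier with consensus-derived labels instead of validated truth
labels (label transfer), and measuring how close the resulting model gets to
a truth-trained one.

## What's inside

* **Variant I/O** — VCF 4.x reading (plain or gzipped) into deduplicated
  call sets keyed by `(chrom, pos, ref, alt)`, multi-allelic splitting, PASS
  filtering, BED region restriction, SNV selection, minimal sorted VCF
  output: `read_vcf()`, `read_bed()`, `restrict()`, `select_snvs()`,
  `write_vcf()`.
* **Consensus engine** — detection matrices and m-of-n voting under
  within-center, cross-center and all-centers grouping, plus pairwise
  intersections: `detection_counts()`, `consensus()`, `build_groups()`,
  `pairwise_intersections()`.
* **Benchmark evaluation** — confusion counts, precision/recall/F1, full
  m-sweep tables with fixed-format TSV reports: `confusion()`, `metrics()`,
  `sweep_m()`, `report_tables()`; the published FD-center reference counts
  ship as `fd_reference_counts()`.
* **Study simulator** — seeded generation of complete multi-center replicate
  studies: truth set with a clonal/subclonal VAF mixture, coverage-dependent
  logistic caller sensitivity, center-level capture of difficult sites, and
  false positives from center-shared, caller-shared and private pools:
  `study_config()`, `simulate_study()`, `estimate_profile()`.
* **Label transfer** — candidate construction with per-caller features,
  chromosome-holdout splitting, a seeded gradient-boosted classifier, and
  the consensus-vs-truth label comparison: `build_candidates()`,
  `train_classifier()`, `label_quality_experiment()`.
* **Pipeline entry points** — `run_simulate()`, `run_consensus()`,
  `run_label_experiment()`, also exposed as subcommands of the
  `inst/exec/replicall` script.

## Worked example

Simulate the default study (3 centers x 3 replicates x 6 pipelines, 1,159
truth SNVs), then sweep the within-center consensus of the low-coverage
center's bwa+Mutect2 replicates:

```r
library(replicall)

bundle <- simulate_study(study_config(seed = 7))
#> StudyBundle: 1159 truth SNVs, 54 call sets (3 centers x 6 pipelines)

truth <- select_snvs(restrict(bundle$truth, bundle$regions))
fd <- bundle$callsets[bundle$manifest$name[bundle$manifest$center == "FD" &
        bundle$manifest$mapper == "bwa" & bundle$manifest$caller == "mutect"]]
sweep_m(fd, truth, expected_truth_size = 1159)
#>   m  tp  fp  fn precision recall    f1  best
#> 1 1 883 491 276     0.643  0.762 0.697 FALSE
#> 2 2 830  42 329     0.952  0.716 0.817  TRUE
#> 3 3 688  24 471     0.966  0.594 0.735 FALSE
```

Read down the table: the union (`m = 1`) catches the most truth variants
(recall 0.762) but drags in 491 false positives; requiring all three
replicates (`m = 3`) is nearly clean but loses a third of the truth set;
majority voting balances the two and wins on F1. Note `tp + fn = 1159` in
every row — each row is scored against the same restricted truth set.

The label-transfer experiment compares a classifier trained on consensus
labels with one trained on the truth:

```r
label_quality_experiment(bundle, scheme = "within_center", m_values = 2, seeds = 1)
#>   label_source label_precision label_recall test_f1
#> 1 consensus_m2           0.955        0.939   0.942
#> 2        truth           1.000        1.000   0.950
```

The consensus-labeled model reaches a held-out-chromosome F1 within 0.01 of
the truth-labeled model, although its training labels were only ~95%
precise and ~94% complete — consensus sets are good enough labels when no
validated truth exists.

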