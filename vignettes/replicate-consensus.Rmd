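---
title: "Replicate-based consensus calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-based consensus calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the consensus model
and its assumptions, the evaluation conventions, the generative model behind
the study simulator, and the design decisions taken where more than one
reasonable choice existed.

## 1. The consensus model

A somatic call set is reduced to a set of variant keys
`(chrom, pos, ref, alt)`. Everything downstream is set algebra on these
keys, so the key definition is the load-bearing convention:

* Multi-allelic VCF records are split into one key per ALT allele. Voting
  needs atomic candidates; a record-level identity would make `C>A` and
  `C>A,G` incomparable.
* Matching is exact equality of all four fields. The classical description
  of this comparison names CHROM, POS, REF and the ID column; the ID column
  of somatic VCFs is almost always `.`, so the only workable fourth
  discriminator is ALT, and that is what the package matches on. We treat
  this as a clarification, not a deviation.
* A FILTER of `.` counts as passing. Unfiltered callers (SomaticSniper
  being the usual example) emit no PASS labels at all and are used
  unfiltered in practice; treating `.` as failing would silently discard
  entire call sets.
* Indel left-alignment is *not* performed. The package's analyses are
  SNV-only (`select_snvs()` runs before any comparison), where
  normalization is a no-op. Feeding un-normalized indel call sets to the
  set algebra would under-count matches; this is a documented limitation,
  not a supported use.

Given call sets $S_1, \dots, S_n$ from biological replicates of the *same*
mapper-by-caller pipeline, the consensus at threshold $m$ is

$$ C_m = \{ v : \#\{ i : v \in S_i \} \ge m \}, \qquad 1 \le m \le n, $$

with $C_1 = \bigcup_i S_i$ and $C_n = \bigcap_i S_i$, and
$C_{m+1} \subseteq C_m$ (anti-monotonicity). The threshold is inclusive
("$m \ge k$"). Because the sets are nested, TP counts are non-increasing
and FN counts non-decreasing in $m$ for any fixed truth set — the test
suite asserts this for randomized inputs, and for $n = 3$ also the exact
identities `union of pairwise intersections = C_2` and
`intersection of pairwise intersections = C_3`.

Votes are never pooled across pipelines: a Mutect2 call and a Strelka2 call
at the same site are different assays of the same hypothesis, and mixing
them changes the question from replicate reproducibility to caller
ensembling. `consensus()` enforces this and offers `allow_mixed = TRUE`
only as an explicit escape hatch for exploration.

Three grouping schemes turn a replicate manifest into voting groups
(`build_groups()`): **within-center** (one group per center and pipeline),
**cross-center** (replicates with the same replicate number, across
centers) and **all-centers** (every replicate of a pipeline, e.g. nine
members for three triple-replicate centers). Centers contributing a single
replicate cannot vote and are excluded from within-center grouping with a
logged notice.

### Attributes on consensus sets

A consensus key inherits the QUAL/VAF/depth attributes of the *first*
contributing call set in manifest order. Nothing in the standard workflow
specifies how merged records should carry attributes; first-source-wins is
deterministic, order-documented, and matches the downstream convention that
classifier features come from the first replicate's files. It is a package
choice, recorded here rather than hidden.

## 2. Evaluation conventions

`confusion()` computes TP/FP/FN by key membership after both sides have
been restricted to the same evaluable regions (BED, 0-based half-open; a
variant at 1-based `pos` is inside `[start, end)` iff `start <= pos-1 <
end`) and SNV-selected. Consequently `TP + FN` is the same for every call
set scored against one restricted truth set — 1,159 in the benchmark
setting this package ships reference counts for — and the suite asserts
this conservation.

`metrics()` keeps full double precision internally. Degenerate ratios
(`0/0`) are reported as 0 with an explicit `*_defined = FALSE` flag rather
than NaN, and F1 is 0 when precision + recall is 0. Report files round
half-even to three decimals (`round()` then fixed-width formatting); every
checkable published cell is consistent with this convention, and the
internal values are never rounded.

Ties in the best-F1 flag of `sweep_m()` go to the smallest `m` — the
cheaper, higher-recall threshold.

## 3. The study simulator

`simulate_study()` generates the complete input side of a multi-center
replicate study. It is first-class, tested code: acceptance-style checks
run *through* it, so its generative model is documented here in full.

**Truth set.** `n_truth` distinct SNVs (default 1,159, echoing the
benchmark's high-confidence exome truth size) are placed uniformly at
random in the evaluable regions — an exome-like layout of evenly spaced
intervals (default 150 intervals of 1,500 bp per chromosome on 8
chromosomes of 2 Mb). Each truth variant gets a VAF from a three-component
Beta mixture: a clonal peak near 0.5 (`Beta(20,20)`, weight 0.35), a
CN-influenced peak near 0.25 (`Beta(10,30)`, weight 0.30) and a subclonal
tail (`Beta(2,12)`, weight 0.35). The mixture CDF is available as `pvaf()`
and the suite checks draws against it (KS distance < 0.05 at $10^4$
draws).

**Sensitivity.** Caller $k$ run on replicate $r$ of center $c$ detects
truth variant $i$ independently with probability

$$ p = \mathrm{logit}^{-1}\!\big(a_k \cdot w \cdot \mathrm{VAF}_i \cdot d_{icr} + b_k + u_{ic}\big) \cdot \kappa_{ic}, $$

where $d_{icr}$ is a per-site Gamma depth draw around the replicate's mean
coverage (shape 6), $w$ a mapper multiplier (bwa 1.0, bowtie 0.95), $u_{ic}$
a center-by-site library effect (Normal, SD 1.2 on the logit scale, shared
across a center's replicates) and $\kappa_{ic} \in \{0,1\}$ a center-level
*capture* indicator described below. `VAF x depth` is the expected
alternate-read mass, the natural argument of a detection curve: the
defaults (`slope`/`intercept` per caller: Mutect2 0.45/-0.8, Strelka2
0.40/-1.0, SomaticSniper 0.30/-0.6) give near-certain detection of clonal
variants at 80x and a soft threshold around 3-5 alternate reads, which is
where real callers live. Setting `slope = 0` makes sensitivity the constant
`plogis(intercept)` — the parameter-recovery tests use this, and
`intercept = Inf` gives the perfect caller of `noiseless_config()`.

**Difficult sites and capture.** A fraction of truth sites (default 0.30)
lies in hard context — low mappability, poor hybridization capture. Whether
a given *center* rescues such a site is a center-level Bernoulli draw
(default probability 0.25) shared across that center's replicates: a
library either covers the locus or it does not, and replicate libraries
from one center are prepared the same way. This is the mechanism that
differentiates the grouping schemes on the recall side. With capture
probability below 1/2, a difficult site is more often rescued by exactly
one center than by two; within-center voting retains such single-center
discoveries while cross-center voting (which needs two centers to agree)
discards them. Under the documented defaults this reproduces the observed
ordering — within-center majority voting is the best-performing scheme —
while remaining an honest mechanism rather than a fitted effect size.

**False positives** come from three pools:

* a *center pool* (default 25 sites, inclusion probability 0.8 per call
  set) shared across one center's replicates and pipelines — library-prep
  artifacts; these survive within-center voting and are exactly what
  majority voting cannot remove;
* a *caller pool* (25-30 sites, inclusion 0.7) shared across centers for
  one caller — systematic caller error; these survive every scheme;
* *private sites*, Poisson per call set (defaults 150/300/450 for
  Mutect2/Strelka2/SomaticSniper), which voting removes almost surely.

Private-FP dominance with small shared pools is what the published
confusion counts look like: union FPs in the hundreds to thousands
collapsing to tens at $m \ge 2$.

**Determinism.** Every stochastic object — truth, each pool, each
center-by-site effect vector, each replicate's depths, each call set —
draws from its own stream, seeded by a fixed string hash of the master seed
and the object's label path. Adding a pipeline, caller or center therefore
never perturbs existing call sets, and a materialized study is
byte-identical across reruns.

**What the simulator does not emulate.** No read-level data (no FASTQ/BAM),
no germline background, no indels or structural variants, no tumor-purity
modeling beyond the VAF mixture, no sequence-context error profiles, and
inter-replicate FP correlations are calibrated only to reproduce *orderings*
(which scheme wins, where the F1 optimum sits), not published effect sizes.
Passing simulation-backed tests therefore says the algorithms behave
correctly under a plausible error structure — it does not certify
performance numbers on real sequencing data.

## 4. Label transfer

The second experiment asks whether consensus sets can replace validated
truth as training labels. Candidates are the union of one replicate's
per-caller call sets plus sampled negatives (default one per called
candidate) from in-region positions no caller touched. Features are
per-caller membership flags and qualities, pooled VAF and depths — every
missing numeric is imputed to 0 with a paired missingness indicator, so
absence is encoded, not conflated with zero. The classifier is a seeded
gradient-boosted tree ensemble (xgboost, depth 4, 60 rounds, single
thread); the claim under test — label quality — is architecture-agnostic,
so a desk-scale tabular model is the right instrument, and read-level deep
models are deliberately out of scope.

Two design points deserve emphasis:

* **No detection-count feature by default.** The count of labeling
  replicates containing a candidate is available
  (`build_candidates(labeling_callsets = ...)`) but excluded from the
  default experiment: when the labels are `count >= m`, that feature *is*
  the label and the comparison would be circular.
* **Chromosome holdout.** Train on the first five chromosomes (karyotype
  order, configurable), test on the rest. All replicates describe the same
  tumor, so any split that mixes chromosomes leaks; the split is validated
  as a true partition. Evaluation is always against truth membership of the
  test candidates — never the training labels. Truth variants absent from
  the candidate union are invisible to every model over those candidates;
  reported test recall is therefore relative to this candidate ceiling,
  which the noiseless and near-noiseless configurations keep close to 1.

## 5. Problem sizes and tolerances

The shipped tests use the sizes at which each question is decidable in
seconds to minutes: brute-force consensus equivalence on 1,000 random
triples; monotonicity on 100 random studies; parameter recovery averaged
over 100 simulations at the full truth size (sensitivity within ±0.03, FP
rate within 3 standard errors); the m-sweep optimum over 100 seeds of the
full default configuration; label-transfer parity (consensus-vs-truth test
F1 gap below 0.05) over 5 seeded repeats. Floating-point identities
(harmonic-mean F1 vs `2TP/(2TP+FP+FN)`) are asserted to 1e-12; counting
identities are asserted exactly.

## 6. Known limitations

* Position-set comparison only: no haplotype-aware matching (vcfeval-style)
  and no genomic-context stratification.
* SNVs only; indel normalization is absent by design.
* Genotypes, phasing, gVCF blocks and CRAM/BAM parsing are out of scope;
  attributes come from VCF fields or the simulator.
* The simulator's shared-pool magnitudes are plausibility choices, not
  fitted parameters; conclusions about real data require real replicates.
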