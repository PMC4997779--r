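---
title: "Methods: multi-omic attribution of TF silencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic attribution of TF silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, thresholds and design decisions behind
`tfsilence`, in the order the pipeline runs them.

## 1. Study design and assumptions

The pipeline works on four phenotypic states: embryonic stem cells (hESC), a
normal differentiated tissue, tumours of the matched cancer type, and the
normal-adjacent samples that accompany them. The underlying biological model
is that bivalent/PRC2-marked TFs that become highly expressed upon
differentiation of a tissue are candidate guardians of that tissue's
identity; their silencing in the matched cancer is treated as the event of
interest, and three in-cis channels — promoter hypermethylation, copy-number
loss, inactivating mutation — compete to explain each silencing event.

Statistical assumptions, stage by stage:

* Differential expression assumes approximately Gaussian log2 expression
  within groups and exchangeable gene-wise variances around a common prior
  (the empirical-Bayes model below). Heavy-tailed contamination is not
  modelled.
* The Z-score silencing call treats the normal-adjacent samples as a
  reference Gaussian per gene. With few normals the plug-in mean/SD inflate
  the tail rate slightly above the nominal 2.3 % (the null-calibration test
  uses 1000 reference samples, where the inflation is negligible; with 20
  normals the null call rate is nearer 3 %).
* Fisher's method assumes independent per-cancer p-values. Cancer types
  sharing a tissue (e.g. the two lung-like cohorts) are independent samples
  here because every cohort has its own tumours and normals; on real data
  shared normals would violate this.
* All correlations between methylation and expression are associative; the
  pipeline makes no causal claim about whether hypermethylation causes the
  silencing or follows it.

## 2. The empirical-Bayes moderated t

Gene-wise variances are modelled as `s² | σ² ~ σ²·χ²_d/d` with
`σ² ~ s0²·d0/χ²_{d0}`. `fit_empirical_bayes()` estimates `(d0, s0²)` by
moments on `log s²`: after subtracting the known `digamma(d/2) − log(d/2)`
offset, the excess of the dispersion of `log s²` over `trigamma(d/2)` equals
`trigamma(d0/2)`, which is inverted numerically. `moderated_t()` then forms
the posterior variance `s̃² = (d0·s0² + d·s²)/(d0 + d)` and refers
`t = Δx̄ / (s̃·√(1/n_a + 1/n_b))` to a t distribution on `d0 + d` df.

Numerical choices:

* Trigamma inversion by monotone Newton iteration (relative tolerance 1e-8,
  at most 100 steps) with a bisection fallback on `[1e-8, 1e8]`; asymptotic
  shortcuts `1/√y` for `y > 1e7` and `1/y` for `y < 1e-6`.
* No excess dispersion (e.g. all variances equal) gives `d0 = ∞` and
  `s0² = mean(s²)`; every gene then uses the prior variance, and p-values
  come from the normal limit of the t distribution.
* `d0 = 0` is the classical pooled t — used as an exactness oracle in the
  tests, which also verify machine-precision agreement with the reference
  Bioconductor implementation on shared inputs.
* Genes with zero between-and-within variance get `t = 0` when the mean
  difference is zero and `±Inf` otherwise, rather than `0/0`.

Two-group significance everywhere is BH-adjusted p < 0.05. The adjustment
choice (rather than an unadjusted cutoff) is the package's own: "significant
differential expression" needs a multiplicity rule, and BH at 0.05 is the
field's default for genome-wide two-group screens.

## 3. Promoter methylation: the recursive model

`assign_promoter_dnam()` gives each gene one beta value per sample: the
unweighted mean over its TSS200 probes; if the gene has none, its first-exon
probes; if none, its TSS1500 probes. Genes with probes only in other classes
(gene body, 3'UTR) are omitted and simply lack the methylation channel
downstream (channel-wise, not row-wise, exclusion). Conventions:

* The region class is decided per gene from the manifest, not per sample.
* A probe annotated to several classes for the same gene counts once, at its
  highest-priority class, preventing double counting.
* A missing beta for one probe in one sample is averaged over the remaining
  probes of the class; the cell is missing only if all are missing.
* Gene-body probes are never used as a last resort; the model stops at
  TSS1500.

The implementation is verified against a brute-force per-gene enumeration
oracle, exactly, on randomized manifests.

## 4. Per-tumour calls and thresholds

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `z_threshold` | −2 | SD of normal expression | per-tumour underexpression call; strict `<` |
| `cnv_threshold` | −0.35 | log2-ratio-like segment value | conservative one-copy-loss bound; strict `<` |
| `hyper_threshold` | 0.3 | Δβ | promoter gains of ≥ 0.3 are the regime where methylation plausibly accounts for silencing; strict `>` |
| `relaxed_threshold` | 0.1 | Δβ | sensitivity regime for the per-TF exclusivity analysis; strict `>` |
| `alpha` | 0.05 | BH-adjusted p | significance for up/down gene selection |
| `n_random` | 1000 | genes | random draw for the up/down fraction comparison |

All four call thresholds are strict inequalities; values exactly at a
threshold never produce a call (tested explicitly). Δβ is used instead of a
methylation Z-score deliberately: a Z-score can be enormous for a tiny
absolute change when normals are homogeneous, and the question is whether
the methylation change is large enough to account for the expression change.

CNV segments map to genes by maximal overlap (ties: the segment with the
smaller start, making runs deterministic); a gene with no overlapping
segment has a missing CNV channel. SEG input is assumed 1-based inclusive
and converted on read — all internal coordinates are 0-based half-open, and
readers are the only conversion point. Mutations count as inactivating when
classed nonsense, missense or deletion (MAF indel classes; splice-site and
other classes map to `Other` and never produce calls), and multiple records
for one gene and tumour collapse to a single call.

## 5. Controls, exclusivity and meta-analysis

**Control genes.** The preferential-silencing comparison needs
non-housekeeping genes expressed like the TFs in normal-adjacent tissue.
Matching is greedy 1:1 nearest-neighbour on mean log2 expression, processing
TFs in decreasing expression order, without replacement, distance ties
broken by lexicographic gene ID. 1:1 matching (rather than a pooled
similar-expression set) was an open design choice; it gives an equal-sized,
individually matched control set and a deterministic algorithm. "Expressed
in the normal tissue" defaults to mean normal-adjacent expression above the
cohort median — a liberal cutoff, configurable, since any "highly expressed"
rule needs a number.

**Mechanism classes.** Over the tumours where a TF is underexpressed, the
fractions with loss / hypermethylation / mutation feed a qualitative class:
DNAm-dominant (`f_hyper ≥ 0.2`, `f_loss < 0.1`), CNV-dominant (symmetric),
Both (both ≥ 0.2), else Neither. The 0.2/0.1 cutoffs are the package's own
reading of what separates the visually distinct groups in
frequency-vs-frequency scatterplots; they are exposed in the function
signature.

**Mutual exclusivity** is probed two ways: (i) ranking TFs by CNV-loss
frequency and testing (one-tailed rank-sum) whether hypermethylation is more
frequent in the lowest tertile than the top tertile, and the mirrored
direction — the rank-sum statistic on frequencies is our choice, tertile
boundaries are taken on mid-ranks so ties stay together, and a tertile left
empty by heavy ties yields NA with a warning rather than a fabricated test;
(ii) per TF, among its underexpressed tumours with ≥ 1 % frequency of both
loss and relaxed hypermethylation, testing whether Δβ is higher in tumours
without CNV loss.

**Meta-analysis.** Per cancer type and channel, silenced TFs are compared
against all other underexpressed genes by one-tailed rank-sum on per-gene
statistics (differential-methylation moderated t; mean segment value;
mutation frequency — the latter two being the package's own choice of
channel summary). Fisher's method combines the per-cancer p-values; exact
zeros are floored at the smallest positive double with a warning instead of
propagating `−Inf`. Cross-cancer concordance uses squared Pearson
correlations of per-TF frequencies over shared silenced TFs, with a paired
one-tailed signed-rank test comparing the methylation and CNV channels
across cancer pairs.

**SVD QC.** Expression matrices are row-centred and decomposed; each of the
top 5 right singular vectors is tested for association with phenotype
(rank-sum for two classes, Kruskal–Wallis otherwise) and the data set is
flagged when the top component does not associate at α = 0.05. The
association statistic is our choice — the procedure this mirrors is
described only qualitatively in the literature — so the flag marks cohorts
for inspection; it does not reproduce any particular published
keep/drop decision.

## 6. The synthetic cohort: what it emulates, and what not

`generate_cohort()` plants, per cancer type, 40 silenced TFs (20
methylation-driven, 10 CNV-driven, 5 both, 5 with no in-cis lesion) among a
tissue's 48 developmental TFs (24 shared by all tissues, 24 exclusive),
inside a universe of 2000 genes with 200 TFs and 200 housekeeping genes; 20
hESC lines, 20 normals per tissue, and 6 cancer types (2+2+1+1 over 4
tissues) with 60 tumours and 20 normal-adjacent samples each. Default effect
sizes: +2 log2 upregulation upon differentiation, −2 log2 silencing in 60 %
of tumours, Δβ gains of 0.4 planted only in the tumours where expression
dropped, planted segment values of −0.5, background mutation rate 0.01,
expression noise SD 0.5 (log2), probe noise SD 0.05 (additive truncated
Gaussian). This scale runs the full pipeline in well under five minutes on
one CPU and leaves all planted effects comfortably detectable — the
generator characterizes correctness, not statistical power at marginal
effect sizes.

Two structural choices make the cross-cancer behaviour realistic. The
hypermethylation event fraction is drawn once per TF (uniform on
0.45–0.75) and shared across cancer types, emulating a common epigenetic
programme, while the CNV event fraction is drawn independently per (TF,
cancer) (uniform on 0.25–0.7), emulating idiosyncratic genomic losses; this
is why methylation frequencies correlate more strongly between cancers than
CNV frequencies. Background downregulated genes (300 per cancer) carry their
own CNV/mutation drivers, so the CNV and mutation meta-channels for TFs are
at or below background — the direction real cohorts show. "Both"-mechanism
TFs plant their two channels in disjoint tumour subsets, i.e. the mutual
exclusivity the per-TF analysis looks for.

Deliberately not modelled: array chemistry (betas are generated
pre-normalized; no type-1/type-2 probe bias correction), chromosomal
architecture (genes are evenly spaced on synthetic chromosomes;
planted loss segments cover single loci), tumour purity, subclonality,
cellular heterogeneity, age-related drift in normal-adjacent tissue, and
trans effects. Passing the recovery tests therefore demonstrates that the
pipeline's statistics and calls are correct and calibrated under its own
model assumptions — not that the pipeline is robust to the artefacts of
real arrays and real tissue composition.

hESC/tissue expression is synthesized directly on the log2 array scale,
while tumour cohorts are synthesized as counts (`round(2^x − 1)`) so the
log2-regularization path (`log2(count + 1)`, removal of all-zero and
zero-variance genes) is exercised; the +1 offset keeps zero counts at zero.

## 7. Degenerate inputs and edge rules

* `rank_sum_test()` enumerates all assignments (mid-ranks for ties) up to a
  total sample size of 12; beyond that, the normal approximation with
  tie-corrected variance and continuity correction 0.5.
* Genes with zero normal-sample variance are dropped from Z-scores with a
  message (their Z would be ±∞); genes never underexpressed are excluded
  from mechanism frequencies.
* `expected_counts_null()` with a single draw collapses its interval and is
  flagged `degenerate`.
* Zero-variance frequency vectors skip a concordance pair for that channel
  only.
* Quantile normalization refuses missing values (filter first), and its
  mid-rank tie rule means a tied column sits slightly off the common
  reference; on tie-free data the transform is exactly idempotent.

## 8. Problem sizes used by the test suite

Unit tests run on reduced instances (hundreds of genes, tens of samples);
the end-to-end recovery and calibration tests use the default cohort above,
5000 genes for empirical-Bayes parameter recovery, 2000 genes for the
null-uniformity check, 100 genes × 1000 reference samples × 400 null
tumours for the Z-call calibration, and 100 repeats of 200 null draws for
the expected-count coverage check. These sizes were chosen so the full suite
characterizes every stage while remaining a routine desk-scale run.
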