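---
title: "Methods: models, conventions and design choices in medipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in medipr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements,
the conventions it had to fix where the field leaves room, and the design of
the synthetic-data generator that its tests are built on. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The measurement model

MeDIP-seq enriches methylated DNA, so aligned-fragment coverage is the
methylation proxy. All coordinates are 0-based half-open (the BED
convention) throughout; GTF input is converted on load, which gives
bit-exact BED round trips. The methylation level of a region is the
depth- and length-normalised coverage

$$\mathrm{RPKM} = \frac{n}{(l/1000)\,(N/10^6)},$$

with $n$ the number of fragments overlapping the region by at least 1 bp,
$l$ the region length in bp, and $N$ the sample's total mapped-fragment
count. The $\ge 1$ bp overlap rule is a convention (a fragment "in" a
region is not otherwise defined for fragments straddling a boundary); a
midpoint-containment rule is available via
`quantify_peak_rpkm(rule = "midpoint")`.

## Peak calling

Peak detection is deliberately simple: it is infrastructure, not the
analysis's contribution. Sliding windows (width 300 bp, step 100 bp) are
scored by the Poisson upper tail $P(X \ge k)$ of their fragment count under
the genome-wide background rate $\lambda = N w / G$, windows with
$p < 10^{-5}$ are kept, and overlapping or book-ended significant windows
are merged into peaks. The window/step defaults are roughly fragment-scale
(fragments default to 250 bp, a typical sonication mean) so a single
enriched locus produces one merged peak. Peaks may also be supplied
pre-computed as a BED-derived tibble, bypassing this stage.

Two conventions are fixed here that a published peak caller would also have
to fix, but that the analysis description leaves open:

* **Pooled peak universe.** Peaks are called on the pooled fragments of all
  samples in a region, then quantified per sample. The per-peak t-test
  requires one common peak universe across the compared samples; pooling is
  the simplest construction that provides it.
* **Genome-wide background.** $\lambda$ uses the total genome length; no
  local background correction is applied. With the synthetic genome's
  unstructured noise this is the exact null; on real data a local-rate
  refinement would be the first extension.

## DMR calling

Per peak, case and control RPKM are compared with a two-sided t-test.
The unequal-variance (Welch) form is the default because group variances
have no reason to be equal when one group carries an effect; the pooled
test is available (`test = "pooled"`). Degenerate peaks where both groups
are constant and equal give $p = 1$; constant-but-unequal groups give
$p = 0$. Significant peaks ($p < 0.01$, raw) are merged when their spacing
is strictly below 50 bp. Two further conventions are ours:

* **Same-direction merging only.** A DMR needs one coherent direction;
  adjacent significant peaks of opposite sign remain separate regions.
* **Span-level re-statistics.** Merged spans are re-quantified as RPKM per
  sample and re-tested, so a DMR's reported means and p-value describe the
  region actually reported rather than an average of its parts. Merged
  regions whose re-test leaves the calling threshold are dropped, keeping
  the invariant that every reported DMR satisfies $p < \alpha$. When the
  fragments are not at hand, the span RPKM is approximated by the
  length-weighted mean of the component peaks.

No multiple-testing correction is applied on the primary path — DMRs are
called at raw $p < 0.01$, matching the pipeline this package re-implements —
but BH-adjusted q-values are reported alongside for transparency.
Comparisons are restricted to samples of a single region; a combined case
group (e.g. both disorders versus controls) is expressed by passing a
vector of group labels.

## Genomic context and enrichment

The element map derives promoters as TSS −2500/+500 bp (strand-aware; the
TSS of a minus-strand gene is its transcript 3′ coordinate in genome
space), introns as transcript span minus exons, UTRs as exonic sequence
outside the CDS when CDS bounds exist, and intergenic space as the
complement. Element membership of a query is multi-label (every class hit
by ≥ 1 bp), because enrichment counting must not hide co-occurring
contexts; a single-label precedence collapse
(promoter > 5′UTR > exon > intron > 3′UTR > intergenic) is provided
separately for stacked-bar summaries. CpG-island shores are the 2 kb
flanks of merged islands (the width follows the established shore
convention; it is configurable), clipped and island-subtracted so islands
and shores are disjoint; context labels use the precedence
island > shore > open sea.

Element enrichment uses matched pseudo-random region sets: one random
region per DMR with the same chromosome and length, start uniform over the
admissible range. The empirical p-value is the add-one estimator
$(g+1)/(n+1)$, where $g$ counts permutations whose overlap is at least
(enrichment) or at most (depletion) the observed one. The add-one form is
used because the raw exceedance proportion can return zero, which is not a
valid p-value; at $n = 1000$ the attainable floor is $1/1001 \approx
0.001$. "Overlap" is the number of regions hitting the class by ≥ 1 bp
(region-level); a bp-level statistic is available
(`statistic = "bp"`). The count statistic takes few distinct values when
region sets are small, and ties with the observed value make the empirical
p conservative in a lumpy way; this is a property of any discrete
permutation statistic, not a miscalibration. The package's calibration
test therefore checks uniformity of the null p on the near-continuous bp
statistic, and checks the count statistic's floor behaviour separately.
Random placement applies no exclusion mask (the synthetic genome needs
none); a mask hook exists for real genomes with assembly gaps.

The CGI-vs-shore association is a 2×2 Fisher exact test of
{real DMRs, one matched random set} × {overlaps island, overlaps shore},
island precedence for regions touching both. The comparison population is
a matched random set because the original contingency construction is not
otherwise specified; the odds ratio is the cross-product with a 0.5
Haldane correction iff any cell is zero. Functional-term enrichment is the
upper-tail hypergeometric test per term with BH adjustment across tested
terms; no expression-level bias correction is applied (a corrected method
is a named non-goal).

## Transcriptome integration

Gene RPKM uses the same formula as peaks with exonic transcript length.
DE calling is by fold change on pseudocounted group means,
$fc = (\bar{x}_{case} + c)/(\bar{x}_{ctrl} + c)$ with $c = 0.25$ RPKM;
without the pseudocount the fold change of a silent gene is undefined. A
gene is DE when $\max(fc, 1/fc) > 1.5$. Welch-test q-values are reported
as a diagnostic only. Methylation-expression coupling is the Pearson
correlation, per element class, of log2 DMR methylation fold change
against log2 expression fold change of the genes the DMR hits through that
class; log transformation symmetrises up/down changes (a raw-ratio mode
exists). A gene with several DMRs in a class contributes one pair per DMR;
classes with fewer than 3 pairs are skipped with a warning.

## The separation diagnostic

The transferability question — does a feature set defined in comparison A
separate cases from controls in cohort B? — is operationalised as: z-score
each feature across the cohort's samples (zero-variance features dropped),
cluster samples on $1 - r$ (Pearson) distance with average linkage, cut the
tree into two, and score the cut against the case/control labels with the
adjusted Rand index. ARI = 1 is "successful separation"; the original
assessment was qualitative (by eye on dendrograms), so the ARI convention
is this package's quantification. Metric and linkage are configurable
(Euclidean, complete linkage).

Two conventions matter here:

* **All features, not top-k, for cross-cohort evaluation.** The top-50
  most-variable selection (`select_top_variable()`) is the
  within-comparison overview. Applied to a cross-region evaluation it
  would rank features by variance *in the evaluation cohort*, promoting
  exactly whichever few features happen to carry signal there, and the
  evaluation would no longer measure whether the *signature* transfers.
  `run_pipeline()` therefore clusters cross-cohort evaluations on the full
  feature set (`separation_top_k = NULL` default).
* **The 2-way cut has a lumpy null.** With 11–18 samples, average-linkage
  trees on pure-noise features occasionally produce cuts that agree with
  the labels up to one or two samples (ARI ≈ 0.3–0.7) purely by chance;
  null simulations in the development of this package put this at roughly
  5–10% of evaluations. Cross-region ARIs should therefore be read as
  "near zero" rather than "exactly zero".

## The synthetic-data generator

The generator's defaults are the study conditions the tests assume, and
they are not tuning knobs: 5 SC / 7 BP / 6 control subjects, each sampled
in two regions; a 5 × 10 Mb autosome set with 300 multi-exon genes and 400
CpG islands (half at TSSs); 800 shared background coverage loci with
log-normal mean fragment counts (median 20, log-sd 0.3) and negative
binomial per-sample counts (size 50 — biological replicates are
overdispersed; a Poisson degenerate case is the size → ∞ limit); 200
injected truth DMRs per region at RPKM ratio 3; 20,000 uniform noise
fragments per sample; fragment length 250 bp.

Structural choices that make the generator faithful to the emulated study
rather than merely convenient:

* **Direction and placement structure.** Region-1 truth is 80%
  hypomethylated with 80% of hypo DMRs placed in the terminal decile of a
  chromosome (the terminal-zone decision is taken first, so the
  end-preference is realised regardless of the other placement weights);
  region-2 truth is 80% hypermethylated, placed genome-wide. 30% of truth
  DMRs are anchored in CpG-island shores and 40% inside gene bodies
  (mostly introns) — the placement weights that make shore association,
  intron enrichment and methylation-expression coupling observable
  downstream. Injected loci keep a 1.5 kb clearance from each other and
  from background loci so two injected effects can never be merged into
  one called peak.
* **Region-specific truth loci.** A truth locus carries coverage only in
  samples of its own region: methylomes differ between tissues, and a
  region's injected peak is simply not part of the other region's peak
  landscape. Beyond realism this guarantees the cross-region evaluation
  is a genuine null — otherwise each comparison's false positives
  occasionally land on the other region's truth loci and leak real signal
  into the transfer test.
* **Depth-equalised libraries.** Sequencers deliver a target depth per
  library regardless of methylome composition, so each sample's total N is
  fixed (per region) and the unstructured noise pool absorbs the fragment
  mass gained or lost at truth loci. At desk scale the injected effects
  are a noticeable fraction of the library — in the emulated study DMRs
  are a negligible fraction of 73M reads — and without this choice RPKM's
  division by N converts the direction asymmetry into a genome-wide shift
  of every null peak, inflating the per-peak type-I error about four-fold
  and breaking the generator's own null-calibration contract.
* **Weak, heterogeneous expression changes.** 100 DE genes per region
  (disjoint across regions) at fold change 2, but with per-subject
  penetrance 0.6 and a latent per-sample expression factor (loading sd
  0.6) on top of negative binomial noise (size 3). Post-mortem brain
  expression is dominated by inter-individual heterogeneity (agonal state,
  PMI, pH, cellular composition); without subject-level structure *any*
  feature set selected for a group difference separates the cohort
  perfectly, because nothing else varies — and the emulated contrast
  (methylation signatures separate, expression signatures do not) would be
  unrealisable. Methylation effects are fully penetrant by design: the
  contrast between stable methylation alterations and labile expression
  changes is the point of the construction. Half of the DE genes are
  drawn from genes whose promoters or introns host truth DMRs, with
  expression direction coupled to methylation direction
  (`coupling_sign = +1` by default), which plants the weak positive
  intron-level methylation-expression correlation the integration stage
  recovers.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: CpG-density-dependent MeDIP efficiency, GC or
mappability bias, read-level errors (fragments are intervals, not
sequences), assembly gaps or blacklist regions, overlapping genes and
alternative promoters, batch effects in methylation, and covariate
structure (age/sex are generated for the sample sheet but drive nothing).
Conclusions about calibration and recovery transfer to real data only to
the extent these absences do not matter for the statistic in question.

## Numerical and degenerate-input conventions

* Metagene bodies are binned fractionally via linear interpolation of the
  cumulative coverage, so features shorter than the bin count are handled
  exactly rather than erroring; minus-strand features are reversed so bin
  order is 5′→3′.
* PCA coordinates fix sign by forcing the largest-magnitude loading of
  each component positive, making output reproducible across runs and
  BLAS builds.
* Top-variable selection breaks variance ties by feature id (ascending) so
  the selection is deterministic.
* Hierarchical clustering drops zero-variance features before z-scoring;
  fewer than two usable features is an error, as is a constant sample
  profile in the correlation QC (reported NA with a warning).
* The generator derives all stage seeds from the single user seed; the
  same seed reproduces every file byte-identically (checksums in the
  bundle manifest), and stage seeds stay within 32-bit integer range.
* Evaluation scales: the bundled acceptance checks run the full 36-sample
  study on the 50 Mb genome (about a minute of DMR calling per region on
  one core), 10,000 null peaks for the type-I check, 1000 permutations for
  enrichment, and 200 repeats at 99 permutations for the calibration
  check — sizes chosen so each check's binomial/KS tolerance is decisive.

## Acceptance evaluation conventions

Recovery and false-discovery are scored on the combined-case analysis
(SC + BP versus controls within each region, n = 12 vs 6): the injected
effects are shared by both disorders, the emulated study itself analyses
the combined groups, and the larger case group puts the Welch test at
p < 0.01 in its high-power regime at these sample sizes. A truth DMR
counts as recovered when a called DMR of the correct direction overlaps it
by ≥ 1 bp; a called DMR counts as a false discovery when it overlaps no
truth region at all.

## Known limitations

* The Poisson scan is a stand-in, not a reimplementation of a published
  peak caller; peak boundaries are window-resolution (±100 bp).
* RPKM inherits its known compositional sensitivity; the generator
  sidesteps it by construction (see above), real data cannot.
* The permutation machinery treats regions as independent; long-range
  correlation of methylation is not modelled in the null.
* The fold-change DE caller has no variance moderation by design (it
  reproduces a threshold rule); its q-value column is diagnostic only.
* The covariate-adjusted (age/sex) re-analysis of DMRs is out of scope;
  the sample sheet carries the covariates for users who want to fit such
  models with standard tools.
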