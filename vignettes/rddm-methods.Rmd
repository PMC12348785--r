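---
title: "Methods: methylome, sRNA and transcriptome integration for RdDM locus discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome, sRNA and transcriptome integration for RdDM locus discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, the numerical
choices made where the design was genuinely open, and the package's known
limitations. Everything quantitative stated here is recomputed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The biological question

In plants, cytosine methylation occurs in three sequence contexts — CG,
CHG and CHH (H = A, C or T) — maintained by different pathways. CHH
methylation at transposable elements and nearby promoters is established
and maintained by RNA-directed DNA methylation (RdDM), in which 24-nt
siRNAs guide de novo methylation. When a promoter TE loses its 24-nt
siRNAs, its CHH methylation decays and the downstream gene can be
released from silencing. The package looks for exactly this tri-omic
signature in a treatment time course (days post treatment, dpt): a CHH
hypomethylated region in a promoter, a downregulated 24-nt sRNA cluster
at the same locus, and an upregulated gene.

## Methylation levels

A cytosine's methylation level is the ratio of reads supporting the
methylated state to total reads at the site; sites without coverage are
undefined, not zero. Global and per-region levels are, by default, the
coverage-weighted pooled ratio `100 · Σ meth / Σ total` over covered
sites of a context. This matches the read-ratio definition of the level
and weights deep sites more; the unweighted mean of per-site fractions is
available (`weighted = FALSE`) and differs when coverage is uneven.

Functional regions are assigned with a fixed precedence so that every
position gets exactly one label: 5′ UTR > 3′ UTR > exon > intron (gene
span) > upstream 2 kb flank > downstream 2 kb flank > intergenic, with
ties among genes broken by smaller gene start and then gene id. The
precedence means gene-body labels beat the flank of a neighbouring gene,
and UTRs beat the exons that contain them; the labelling is invariant
under permutation of the gene list (a property test asserts this).
Because "TSS region" has no canonical width, DMR localisation reports it
as `tss ± tss_window` (default 1000 bp, configurable in `region_spec()`),
and the summary records that label separately from the partition by
exon/intron/UTR/flank.

A context call needs the strand-oriented downstream bases: CG is decided
by one downstream base, CHG/CHH need two. A site too close to the
sequence end (or with an N in the required window) gets an `NA` context
and is excluded from levels and DMR calling but retained in enumeration.

## DMR calling

The genome is tiled into non-overlapping windows (`tile_width`, default
1000 bp — also the sRNA cluster width, so the two layers share a
coordinate grid). Within each group the replicates' methylated and total
counts are pooled per window; a window is tested only when both groups
have pooled coverage of at least `min_coverage` (default 30 reads). The
test is a two-sided Fisher exact test on the 2×2 table of
methylated/unmethylated counts, followed by Benjamini–Hochberg correction
across all tested windows of the same context (CG, CHG and CHH are
separate families because results are reported per context). A tested
window is a DMR when all of the following hold:

* `q ≤ fdr` (default 0.05),
* the absolute level difference exceeds `min_diff` (default 15
  *percentage points* — the difference of levels, not a ratio; the ratio
  sense is covered separately by the fold-change clause),
* the level ratio (treatment/control) is at least `fc_hi` (default 2) or
  at most `fc_lo` (default 0.5).

Polarity is *hyper* when the difference is positive. A window whose
control level is zero but treatment level positive has infinite fold
change and passes the upper bound; a window with both levels zero is
never a DMR. Because `fc_lo = 1/fc_hi` and the Fisher p is invariant
under swapping the two rows, exchanging the treatment and control groups
flips every DMR's polarity and negates its difference while leaving p and
q unchanged — an acceptance property.

Two assumptions are worth stating. Pooling replicates before the Fisher
test treats reads within a group as exchangeable; with two replicates per
timepoint a replicate-aware dispersion model is not estimable, and the
pooled test is deterministic and matches pooled-mode DMR callers. And the
Fisher test assumes binomial counts, so between-replicate overdispersion
inflates its nominal significance; the effect-size filters (15 pp, 2-fold)
are what keep the false-positive rate near zero in practice, which the
null-genome acceptance check measures.

The Fisher p itself is computed by a vectorised enumeration of the
hypergeometric support (summing all outcomes no more probable than the
observed table, with the conventional `1 + 1e-7` tie tolerance). Batches
of windows sharing margins share one enumeration, which keeps exhaustive
verification cheap: the test suite compares it against an independent
log-gamma enumeration for every 2×2 table with row margins up to 60, and
against `stats::fisher.test` on random tables.

## sRNA clusters, DSRs and DEGs

Reads of 18–30 nt are assigned to the 1-kb bin containing their 5′ end
(each read counts once; bin k covers positions `[k·w+1, (k+1)·w]`,
1-based inclusive, and ids are rendered `chrom;start;end`). Size classes
are "20–22 nt" (lengths 20, 21, 22 pooled), "24 nt" (exactly 24), and
"all"; other lengths contribute only to "all".

Counts are CPM-normalised — `count · 10⁶ / library size` — with the
library size of a size-class test taken from the *full* per-sample read
total, so class-level CPMs remain comparable across classes. The
differential test is a Welch two-sample t-test on `log2(CPM + 1)`; the
log2 fold change is the difference of group means on that scale (the +1
pseudocount avoids log 0 and was chosen over a smaller offset for
stability at low counts). BH correction is applied across one *family*:
all size-class tests of the same cluster set form one family, and genes
form their own. A feature is `up` when `q ≤ 0.05` and `log2FC ≥ 1`,
`down` mirrored, `ns` otherwise. With fewer than two replicates in a
group no p-value exists; the direction is then decided by the fold change
alone and flagged `underpowered`. Gene expression uses the same audited
code path (`call_degs()`); the threshold is applied to the BH-adjusted q
at 0.05, with a raw-p mode behind a flag. A dispersion-moderated
negative-binomial test could be substituted behind the same interface but
is deliberately out of scope: one simple, fully specified test keeps the
pipeline auditable.

### Power of the Welch t at n = 3 — and what it implies

With three replicates per group, negative-binomial dispersion 0.1 and a
true |log2FC| of 2, the per-feature noncentrality of the Welch t is about
5.4 at roughly 4 degrees of freedom: the single-test power is about 0.9
at p ≤ 0.05 but falls below 0.7 at p ≤ 0.02 and below 0.5 at p ≤ 0.01.
Under BH the effective per-feature threshold is `0.05 × (fraction of the
family rejected)`, so attainable recall solves a fixed-point equation and
is bounded near 0.85 even when nearly every feature carries signal — and
collapses when signal is sparse. Three design consequences follow, all
visible in the code and tests rather than hidden:

* The *recovery benchmarks* plant signal in most features (≈ 80–95 %), so
  they measure the caller near its intrinsic sensitivity; their recall
  thresholds (0.8) sit below the ≈ 0.85 ceiling. Null calibration is
  measured on a separate fully-null simulation.
* The *default* simulation plants differential expression in about half
  the genes and clusters — in line with a strong whole-organism stress
  response — and its end-to-end screen therefore recovers only part of
  the planted RdDM loci: each locus needs both its DSR and its DEG call
  to clear BH, a conjunction with probability well below 1 at n = 3. The
  screen's *specificity* is unaffected (no decoys pass), and the
  acceptance script reports both counts.
* The t-test on discrete counts at n = 3 is conservative: its true size
  is about 0.03–0.04 at nominal 0.05. The null-calibration check
  therefore uses a family small enough (400 genes) that the 3-standard-
  error band around 0.05 honestly reflects this uncertainty.

## Association and the candidate screen

For a stratum (DSR direction × DMR polarity), the 2×2 table over the
background of all *tested* clusters counts direction × overlap
membership; the background is tested clusters rather than all genomic
bins, since empty bins would dominate otherwise. The odds ratio is
`(a·d)/(b·c)` with the Haldane–Anscombe +0.5 correction applied to all
cells only when some cell is zero; significance is the same Fisher exact
test, reported as −log10 p. A cluster overlapping both a hyper- and a
hypo-DMR contributes to both strata. Inverting either factor of the table
(not transposing it — a transpose leaves both OR and p unchanged)
inverts the OR and preserves p.

The promoter is strand-aware: 2 kb upstream through 500 bp downstream of
the TSS, clamped to the chromosome. A *DMR target gene* is any gene whose
promoter overlaps a DMR by at least one base; both the full target list
and the DEG-joined view are emitted, since "target" can reasonably mean
either. The candidate screen then demands, on one comparison, (i) a
promoter-overlapping CHH hypo-DMR, (ii) a downregulated 24-nt DSR cluster
overlapping that DMR *or* the promoter — the sRNA source region is often
adjacent to, not congruent with, the hypomethylated window — and (iii)
an upregulated gene; a TE flag records promoter TE overlap. The mirror
mode swaps all three polarities and is provably disjoint from the
canonical mode. Genes with several qualifying promoter DMRs yield one
record per DMR (the most significant qualifying cluster is kept), with a
deduplicated per-gene view available.

Term enrichment is a flat gene-to-term hypergeometric upper-tail test
with BH across terms; ontology structure (parent-term propagation) is
deliberately not modelled.

## The synthetic-data generator

The generator emulates the study conditions of a cold-treatment
microspore time course on a toy genome (default: two 500-kb chromosomes,
500 genes on a regular slot grid, 300 TEs covering roughly a tenth of the
genome):

* **Methylome.** Site coverage is Poisson(30); the methylated count is
  beta-binomial around the site mean with intra-class correlation 0.05
  (biological replicates of methylomes are overdispersed; `rho = 0`
  recovers pure binomial noise, and a test checks the closed-form
  variance). Site means come from a compartment model: an elevated TE
  compartment (CG 85 %, CHG 60 %, CHH 15 %) and a background solved so
  that the *expected genome-wide pooled level equals the configured
  target* (CG 57.55 %, CHG 30.23 %, CHH 4.6 % at 0 dpt) despite the TE
  and planted compartments — the acceptance calibration check recovers
  these targets within three standard errors.
* **Planted DMR windows** are tile-aligned 1-kb windows with their own
  baselines: hypermethylated windows start low (e.g. CHH at the genomic
  base level) and gain 40 pp; hypomethylated windows start high (CG 75 %,
  CHG 60 %, CHH 45 % — the CHH value typical of an RdDM-target TE) and
  lose 40 pp, clamped to [0, 100]. The high hypo baselines are necessary,
  not cosmetic: a hypomethylated shift can only exceed the 15-pp filter
  and the 2-fold filter if the starting level is well above 15 % and the
  end level below half of it. Treatment effects apply at half amplitude
  at the middle timepoint and full amplitude at the last, emulating a
  monotone response.
* **sRNA.** Cluster totals are negative-binomial (dispersion 0.1) around
  lognormal baselines, split over an 18–30 nt mixture whose 24-nt weight
  rises with treatment (0.35 → 0.55) while the 20–22 nt weight falls.
  Planted DSR clusters shift *every* length class by `2^(±2·amplitude)`
  and keep the control mixture, so their 24-nt log2FC is exactly the
  configured effect.
* **Expression.** Gene counts are negative-binomial around lognormal
  baselines; planted DEGs shift by `2^(±2·amplitude)`.
* **Composition neutrality.** Plain CPM is sensitive to unbalanced
  differential composition: if upregulated mass is not matched by
  downregulated mass, every null feature's CPM shifts. The generator
  therefore plants equal numbers of up- and downregulated features
  (counting the RdDM loci toward their polarity) and draws downregulated
  features' baselines from a `2^|lfc|`-scaled distribution — highly
  expressed features get turned down — making the expected library mass
  invariant at full amplitude. A modest residual imbalance remains at the
  half-amplitude timepoint and is accepted.
* **Coupling.** RdDM loci are planted at the locus level: one slot's
  first tile carries the TE, the CHH hypo window and the 24-nt cluster,
  and the slot's gene (always forward-strand, TSS placed so the window
  falls inside the promoter) is an up-DEG. Planted features of different
  kinds occupy disjoint slots, with a one-slot buffer around RdDM loci
  excluded from every other planted set, so a decoy can only arise from
  at least two simultaneous false-positive calls.
* **Replicates.** WGBS has two replicates per timepoint (matching how
  such time courses are typically sequenced, and the DMR caller's pooled
  design); sRNA and RNA have three, the minimum at which a t-test
  per-feature p exists with any robustness.
* **Determinism.** One master seed derives independent sub-streams for
  genome sequence, gene layout, TEs, methylome, sRNA and expression, so
  changing one module's size does not perturb another's draws; two runs
  with the same seed are byte-identical end to end (an acceptance
  property), and all emitted files (FASTA, GFF3, BED, CX reports, TSVs)
  re-parse through the package's own readers.

What the generator does **not** emulate: read-level artefacts (mapping,
bisulfite conversion errors, PCR duplicates), realistic chromosome
organisation or TE families, linked methylation between neighbouring
sites, isoform structure, or any correlation between layers beyond the
planted loci. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct and calibrated under its stated noise model —
not that the thresholds are optimal for any particular real dataset.

## Numerical and interface choices

* All interfaces are 1-based inclusive; BED input is converted on load.
  Cluster ids use the `chrom;start;end` convention.
* Fold change at zero control level is +∞ (passes the upper bound);
  0/0 never passes. BH is `stats::p.adjust(method = "BH")`, verified
  exactly against a sort-based step-up oracle.
* The window-coverage rule is interpreted per window per pooled group
  (≥ 30 reads); covering every cytosine at ≥ 30 in each sample would
  discard most of a 30× dataset.
* GFF3 genes with several transcripts use the first mRNA (smallest
  start, then id); genes without UTR features simply have empty UTR sets.
* Welch p-values come from `stats::t.test` per feature; a degenerate
  feature with zero variance in both groups gets p = 1 when the means
  are equal and p = 0 otherwise.
* Test problem sizes are chosen to exercise at least 10,000 sites per
  context for calibration, 30 planted windows for DMR recovery, and
  150–190 planted features for DSR/DEG recovery, with fixed seeds
  throughout.

## Known limitations

* The DMR test ignores replicate-level overdispersion (pooled Fisher);
  its nominal p-values are anti-conservative and only the effect-size
  filters make the caller specific. Smoothing-based or dispersion-
  modelled callers are out of scope.
* DSR/DEG power at n = 3 is intrinsically capped (see the power section);
  the tri-omic screen inherits the product of two such powers, so
  end-to-end sensitivity on default-density data is partial even though
  specificity is excellent.
* Plain CPM is composition-sensitive; on real data with strongly
  unbalanced regulation a robust scale factor (TMM or median-of-ratios)
  would be preferable, but the simpler normalisation is kept as specified
  behaviour.
* Term enrichment ignores ontology structure. Alternative transcripts,
  splice-aware logic and chromatin tracks are not modelled.
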