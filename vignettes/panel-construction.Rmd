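---
title: "Constructing and validating an allele frequency panel"
author: "panelforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating an allele frequency panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
library(data.table)
```

# The problem

A population allele frequency panel publishes, for every variant site
observed in a cohort, the alternative allele count (AC), the total number of
called alleles (AN) and their ratio (AF) — population-level summaries that
can be shared when individual genotypes cannot. Building one from thousands
of whole genomes raises four methodological problems this package
implements and tests:

1. joint genotyping across the cohort is too large to run in one piece, so
   it must be **chunked** without changing the result;
2. the X chromosome mixes **diploid and haploid** contexts depending on
   sample sex and position (pseudoautosomal regions);
3. the mitochondrial genome is **circular**, so any linearization corrupts
   calls near its breakpoint;
4. the cohort must be cleaned of **related samples and karyotype
   anomalies**, and the resulting panel validated against independent
   genotyping and other panels.

# Joint aggregation and chunked execution

The cohort-level caller (`jointGenotypeRegion()`) is a deliberate
simplification: it aggregates per-sample records that already carry
genotypes and phred-scaled likelihoods, emitting a site wherever at least
one genotype carries an alternative allele. Allele lists are merged across
samples and ordered by pooled allele depth (ties by allele string), and each
genotype is re-expressed in the merged indexing. It does not realign or
reassemble reads — the package's contribution is the orchestration around a
caller, not the caller itself. Because the aggregation is deterministic in
its inputs, it supports an exact transparency guarantee.

`runChunked()` partitions a contig into `chunkSize` chunks (default 3 Mb)
overlapping by `overlap` bases (default 1 kb), calls each chunk over all
samples, and concatenates. Each overlap is a built-in consistency probe:
a position must be reproduced with identical reference, ALT list and full
per-sample genotype vector by both chunks, or it is removed from the panel
and listed in the discordance report. A call present in only one chunk's
copy of an overlap is also treated as discordant — the conservative,
symmetric reading. The tests verify both directions: on identical inputs
the chunked result is bit-identical to a single-pass run with an empty
report, and an injected perturbation of one chunk's input is recovered
exactly as the set of removed-and-reported sites. The last chunk is simply
allowed to be shorter; redistributing chunk sizes would buy nothing and
complicate the recurrence `start[k+1] = end[k] - overlap + 1`.

Site annotations mirror the standard variant-filtration inputs: `QD`
(a QUAL proxy normalized by the depth of ALT-carrying samples), `FS`
(−10·log10 of the two-sided Fisher exact p on the pooled ref/alt ×
forward/reverse table; the standard "sum of tables no more probable than
observed" definition, not mid-p), `SOR` (symmetric odds ratio with +1
pseudocounts), `DP` and `InbreedingCoeff` (1 − observed/expected
heterozygotes among diploid called samples). The QUAL proxy is the sum over
ALT-carrying samples of the gap between their two smallest PL values,
capped at 99 per sample — monotone in evidence and fully specified, but a
stand-in: upstream QUAL definitions vary, so it is labelled as a proxy in
the outputs. Mixture-model recalibration is replaced by `applyHardFilters()`
— computed annotations plus configurable thresholds, independent SNV and
INDEL rule sets, defaults empty — because a recalibrator needs external
training resources that have no desk-scale equivalent. `MQ` and the
rank-sum annotations require read alignments and are not computable here;
they are accepted as pass-through input annotations when present. This is a
documented limitation.

# The X chromosome and two PAR conventions

Ploidy is resolved by `PloidyMap` from (sex, position): females diploid
everywhere on the X; males diploid in PAR1/PAR2 — plus the XTR under the
`THREE_PAR` convention — and haploid elsewhere; everyone haploid on the
mitochondria. AN accounting follows directly: at a non-PAR site,
`AN = 2·(called females) + (called males)`; in a PAR, `AN = 2·(all called)`.
The package asserts, in every run of its frequency computation, that no
haploid context carries a heterozygote.

Read-level workflows realize the two conventions by re-mapping reads to an
XTR-masked reference. Without reads, `prepareXRecords()` reclassifies the
same positions instead: a male diploid record at a position the convention
treats as haploid is collapsed to the allele with the larger allele depth
(ties to the lower index), and a haploid record in a context the convention
treats as diploid becomes a homozygous diploid genotype. This is the
desk-scale equivalent; it reproduces the defining observable — the two
panels are identical outside the XTR and differ inside it — which the test
suite checks. The convention is applied to males only; female calls are
diploid regardless, so masking cannot change their ploidy.

`xtrHeterozygosityScan()` provides the evidence view: non-overlapping
windows of array markers, male het rate per window. In X-specific sequence
a male cannot be heterozygous, so at zero genotyping error the rate is
exactly 0 outside pseudoautosomal-behaving segments and elevated inside
them — the three-peak shape that motivates treating the XTR as a candidate
PAR. The full-scale GRCh37 coordinates ship as a preset
(`grch37XRegionMap()`); synthetic runs use a 1/100-scale map
(`scaledXRegionMap()`) with the same proportional layout so desk-scale runs
finish in seconds.

The Y chromosome is carried only as depth evidence for sex inference; no Y
variant panel is produced.

# Circular mitochondria

`callMtPanel()` consumes haploid calls from two linearizations of the
circular genome: the reference breakpoint and one shifted by 10,000 bases
(heteroplasmy is out of scope; the mitochondria are treated as strictly
haploid). Shifted coordinates map back by the bijection
`((pos + shift − 1) mod L) + 1`. Within `edgeMargin` bases of the primary
breakpoint the merged panel takes the shifted calls (which are interior
there); elsewhere it takes the primary calls. `edgeMargin` defaults to 300
bases — the scale of a read length, the footprint of breakpoint artefacts —
and is configurable; no canonical value exists. Preferring the
breakpoint-distant linearization on each side also settles what to do with
conflicting calls: each set is consulted only where it is trustworthy. The
decisive property, verified exhaustively in the tests, is rotation
invariance: pre-rotating the entire input by the shift and re-calling gives
the identical merged panel after remapping.

# Sample QC

**Sex inference** uses the method-of-moments X inbreeding coefficient on
non-PAR markers, `F = (obsHom − expHom)/(m − expHom)` with
`expHom = Σ(1 − 2p(1−p))`, thresholds 0.8 (male if ≥) and 0.2 (female
if ≤). The Y/autosome depth ratio must agree (≥ 0.3 for male, ≤ 0.1 for
female); disagreement yields `ambiguous`. This is also the
irregular-karyotype guard: an XO-like sample is homozygous across the X
(F ≈ 1) yet has no Y depth, a contradiction that excludes it. Exact
clinical karyotyping criteria are not published for this workflow; the
F/Y-consistency rule is this package's operationalization.

**Relatedness** is the method-of-moments IBD decomposition: IBS 0/1/2
counts over shared non-missing markers, expected IBS probabilities from
allele frequencies with finite-sample allele-count corrections, Z solved by
moments, clipped to [0,1] and renormalized, `PIHAT = Z2 + Z1/2`. The
estimator assumes independent markers, so it is fed LD-pruned autosomal
dosages (reusing `ldPrune()`), and a single estimate is produced per pair.
`pruneRelatives()` removes relationships closer than third degree using the
threshold 0.1875 — the midpoint between the second-degree (0.25) and
third-degree (0.125) expectations, configurable since no canonical cutoff
exists. Removal is greedy by over-threshold degree (ties: lower call rate,
then lexicographic id) rather than pairwise drop-one: deterministic and
minimal on small graphs; a deliberate, documented deviation from the
common tool's behaviour. The kept set is re-audited on every run.

# Validation machinery

**Concordance** (`concordanceMatrix()`) cross-tabulates WGS and array
states over NotObserved / NoCall / HomRef / Het / HomAlt; the
(NotObserved, NotObserved) cell is undefined. Alleles are harmonized by
attempting a ref/alt swap before excluding a marker; strand flips are not
attempted (the generator never produces the ambiguity). The concordance
ratio divides the genotype diagonal by all jointly-called observations —
no-calls are excluded from the denominator, a choice the ratio's symmetry
argument favours, though other denominators are defensible.

**Cross-panel comparison** (`comparePanels()`) matches per-ALT keys (with
swap harmonization and AF complementation), reports the Pearson correlation
of shared AFs, and annotates outliers — `|ΔAF| ≥ 0.3` by default, a
configurable convention since outliers are a visual notion in scatter
plots — with any overlapping region mask (e.g. a low-complexity BED) or
"Unknown".

**Ts/Tv** is counted per ALT (a multiallelic A→G,T site contributes one
transition and one transversion), undefined rather than 0 without
transversions, and female-only on the X.

**Population structure**: the Hardy–Weinberg exact test is the standard
conditional test on heterozygote counts (no mid-p correction, matching the
thresholds' usual semantics); filters apply MAF, HWE-p and missingness with
a first-failure reason log; `ldPrune()` implements window/step/r²
pruning with window and step in variant counts (the familiar
`--indep-pairwise 200 4 0.1` form), removing the lower-MAF member of each
offending pair and re-auditing the kept set on every run; PCA standardizes
by `(d − 2p)/sqrt(2p(1−p))`, eigen-decomposes the sample covariance, and
fixes signs so each component's largest-magnitude coordinate is positive.
Missing dosages are mean-imputed after filtering — with the missingness
filter at 1% the choice is low-impact.

# The synthetic cohort

```{r, eval = FALSE}
spec  <- cohortSpec(nSamples = 100, seed = 1)
truth <- simulateTruth(spec)
```

`cohortSpec()` defaults are the package's reference study conditions:

| parameter | default | rationale |
|---|---|---|
| `nSamples`, `sexRatio` | 100, 0.5 | mixed-sex cohort at desk scale |
| contig plan | 1 Mb autosome, 1/100-scale X, 16,569 b MT | proportional X layout; real mitochondrial length |
| `afAlpha`, `afBeta` | Beta(1, 3) | low-frequency-skewed site spectrum, as population sequencing shows |
| `errorRate`, `arrayErrorRate` | 0.01 | ~1% genotyping discordance scale |
| `arrayMarkerFraction`, `arrayNoCallRate` | 0.5, 0.01 | array covers a marker subset with rare no-calls |
| `depthMean`, `depthOverdispersion` | 30×, 0.1 | typical WGS coverage, mildly overdispersed |
| `mapq0Fraction`, `mapq0Repeat`, `repeatFraction` | 0.01, 0.5, 0.05 | multi-mapping concentrated in designated repeats |
| `plScale` | 30 phred | one genotype-quality step per likelihood rank |

Genotypes are Hardy–Weinberg draws from the site frequency: two draws in
diploid contexts, one in haploid ones. Relatives overwrite tail samples:
duplicates copy, children take one allele per parent (with X and MT
transmission following the sexes), and second/third-degree relatives share
one allele identical-by-descent at 50%/25% of autosomal sites — exactly the
sharing profile the IBD estimator is supposed to recover. The error model
is a symmetric single-step flip (hom↔het, or allele toggle when haploid):
one parameter, sufficient to exercise the concordance machinery; no
published confusion matrix exists for the arrays being emulated, so error
rates are free parameters. A `bqsrLike` toggle perturbs PL values without
ever changing the likelihood argmax, emulating a recalibration step whose
effect on genotype calls is nil — the tests verify the concordance matrix
is bit-identical with it on or off.

What the generator does **not** emulate: read-level artefacts (no
FASTQ/BAM), linkage disequilibrium haplotype structure (an adjacent
duplicated-variant device supplies r² = 1 pairs for pruning tests),
reference errors, strand-flip ambiguity, or batch effects. Passing tests
therefore demonstrate the pipeline's bookkeeping and statistics are exact
under the stated model — not that real data meet the model.

# Problem sizes and numerical choices

The shipped checks use these scales, chosen so each property is measured
where its statistics are stable: chunking transparency on a 10 Mb contig
with 200 samples and 5,000 sites; mitochondrial checks at the real
L = 16,569 with an exhaustive bijection sweep; X accounting on a
100-sample mixed cohort; Hardy–Weinberg against enumeration for all
genotype configurations with total ≤ 25; FS against enumeration for all
2×2 tables with margins ≤ 30 (within 1e-9); PIHAT at ~10,000 LD-pruned
markers, where the estimator's sampling noise is well inside the
relationship-degree gaps; concordance calibration at ~55,000 jointly-called
genotypes; PCA separation at 200 samples × 2,000 variants with
Balding–Nichols divergence Fst = 0.1. Two-sided exact p-values use the
`≤ observed·(1+1e-7)` tie rule shared by the common implementations;
Hardy–Weinberg probabilities are computed in log space and normalized
before comparison; LD-pruning and relative-pruning post-conditions are
`stopifnot`-asserted inside the functions, not only in tests.

# Known limitations

- The aggregation trusts input genotypes/likelihoods; it cannot rescue
  miscalled records, and QUAL is a declared proxy.
- `MQ`/rank-sum annotations are unavailable without alignments.
- IBD assumes a homogeneous population; admixture inflates PIHAT.
- The PAR-convention reclassification models calling-ploidy effects, not
  mapping effects of reference masking.
- Heteroplasmy, haplogroups, Y variants, annotation (gene consequences,
  rs ids) and web distribution are out of scope.
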