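# panelforge

Builds population **allele frequency reference panels** — per-site AC/AN/AF
tables distributed as VCF — from per-sample variant call files, together with
the quality-control analyses that validate such a panel. It is aimed at
groups constructing cohort-level frequency resources from whole-genome
sequencing who cannot share individual-level genotypes, and at anyone who
wants a tested, desk-scale model of that pipeline.

## What it implements

**Panel construction.** Per-sample VCF records (GT/PL/DP/AD plus per-allele
strand counts) are aggregated by likelihood-argmax joint genotyping into
cohort-level variant sites. Contigs are processed in 3 Mb chunks with 1 kb
overlaps; calls in an overlap that are not reproduced identically by both
adjacent chunks are removed and reported, so chunked execution is provably
equivalent to a single pass. Multiallelic sites are retained (one AC/AF per
ALT). For each site with called allele set `G`,

    AN = sum over called samples of ploidy,  AC_k = #{alleles = ALT_k},
    AF_k = AC_k / AN.

**Sex-aware X chromosome.** Ploidy is resolved per (sample sex, position):
females are diploid across the X; males are diploid in PAR1
(60,001–2,699,520), PAR2 (154,931,044–155,260,560) and — under the
`THREE_PAR` convention — the X-transposed region XTR
(88,456,802–92,375,509), haploid elsewhere. Panels are built under both
conventions; a windowed male-heterozygosity scan of array genotypes locates
the pseudoautosomal-behaving segments that motivate the dual treatment.

**Circular mitochondria.** The circular genome is linearized twice, the
second time with the breakpoint shifted by 10,000 bases. Haploid panels are
called on both, the shifted calls are remapped by
`pos -> ((pos + shift - 1) mod L) + 1`, and sites near the primary
breakpoint are taken from the shifted set, removing edge artefacts.

**Sample QC.** Sex inference from the method-of-moments X inbreeding
coefficient `F = (obsHom - expHom) / (m - expHom)` cross-checked against the
Y/autosome depth ratio (disagreement — e.g. an XO-like karyotype — yields
`ambiguous` and exclusion); pairwise relatedness via the method-of-moments
IBD decomposition (`PIHAT = Z2 + Z1/2`, with finite-sample allele-count
corrections) on LD-pruned markers; greedy pruning of pairs with
PIHAT ≥ 0.1875 (between the 2nd- and 3rd-degree expectations).

**QC analyses.** WGS-vs-array 5×5 genotype concordance matrices and
concordance ratios; cross-panel AF comparison with Pearson correlation,
ref/alt harmonization and mask-annotated outliers; per-ALT Ts/Tv ratios
(female-only on the X); site annotations (QD, FS from the two-sided Fisher
exact strand test, SOR, InbreedingCoeff) with configurable hard filters;
mean-depth accessibility tracks under all-reads and MAPQ ≥ 20 policies.

**Population structure.** Hardy–Weinberg exact test, MAF/HWE/missingness
variant filters, merging of datasets on common variants, LD pruning
(`--indep-pairwise 200 4 0.1` semantics), and PCA on the
`(d - 2p)/sqrt(2p(1-p))`-standardized genotype matrix.

**Synthetic cohorts.** A seeded generator (`cohortSpec()` /
`simulateTruth()`) emulates everything the pipeline assumes —
Beta-distributed allele frequencies, Hardy–Weinberg genotypes, sex-linked
ploidy, Mendelian relatives and duplicates, genotyping error, array no-calls,
negative-binomial depth with a MAPQ-0 mixture — so the whole pipeline runs
and is tested end-to-end without any protected data.

## Worked example

```r
library(panelforge)
library(data.table)

spec    <- cohortSpec(nSamples = 50, nSitesPerContig = 500, seed = 7)
truth   <- simulateTruth(spec)                 # 50 samples; autosome, X, MT
records <- rbindlist(cohortRecords(truth))     # per-sample GVCF-like records
pmap    <- PloidyMap(truthSexes(truth), spec@xmap)

run <- runChunked(records[contig == "1"], "1", 1e6, pmap,
                  chunkSize = 3e5, overlap = 1000)
run$discordantCount
#> [1] 0
panel <- computeFrequencies(run$callset)
head(panelEntries(panel), 3)
#>   contig  pos ref alt altIndex ac  an   af multiallelic filter
#> 1      1 1067   A   G        1 15 100 0.15        FALSE   PASS
#> 2      1 2002   C   T        1 21 100 0.21        FALSE   PASS
#> 3      1 2861   A   C        1 31 100 0.31        FALSE   PASS
tsTvPanel(panel)
#>   group  ts  tv    ratio
#> 1   all 329 159 2.069182
```

`discordantCount` is the number of overlap-zone calls discarded because the
two adjacent chunks disagreed (0: chunking was transparent). Each panel row
is one ALT allele: 15 of 100 called alleles at 1:1067 are `G`, so AF = 0.15
with every sample diploid and called (AN = 100). The Ts/Tv ratio ≈ 2 is the
generator's transition:transversion mix and doubles as a sanity statistic,
as it does for real call sets. `writePanelVcf(panel, "panel.vcf")` emits the
distributable `AC/AN/AF` VCF; `buildXPanels()` and `callMtPanel()` produce
the X-chromosome (both PAR conventions) and mitochondrial panels the same
way.

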