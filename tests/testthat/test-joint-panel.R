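test_that("joint aggregation preserves calls at a shared biallelic site", {
  recs <- rbind(recRow("s1", 100, a1 = 0L, a2 = 1L, ad = "10,10"),
                recRow("s2", 100, a1 = 1L, a2 = 1L, ad = "0,20"))
  cs <- jointGenotypeRegion(recs, Region("1", 1, 1000),
                            femalePmap(c("s1", "s2")))
  expect_equal(nSites(cs), 1)
  expect_equal(cs@sites$alt, "G")
  expect_false(cs@sites$multiallelic)
  expect_equal(as.vector(cs@A1), c(0L, 1L))
  expect_equal(as.vector(cs@A2), c(1L, 1L))
})

test_that("distinct sample alleles merge into one AD-ordered multiallelic site", {
  recs <- rbind(recRow("s1", 100, alt = "T", a1 = 0L, a2 = 1L,
                       ad = "10,10"),
                recRow("s2", 100, alt = "C", a1 = 1L, a2 = 1L,
                       ad = "2,18"))
  cs <- jointGenotypeRegion(recs, Region("1", 1, 1000),
                            femalePmap(c("s1", "s2")))
  # pooled AD: C (18) before T (10); genotypes re-indexed accordingly
  expect_equal(cs@sites$alt, "C,T")
  expect_true(cs@sites$multiallelic)
  expect_equal(as.vector(cs@A1), c(0L, 1L))
  expect_equal(as.vector(cs@A2), c(2L, 1L))
  # no-call sample stays NA; hom-ref-only site never appears
  recs2 <- rbind(recRow("s1", 50, a1 = 0L, a2 = 0L),
                 recRow("s2", 50, a1 = 0L, a2 = 0L),
                 recRow("s1", 70, a1 = 1L, a2 = 1L))
  cs2 <- jointGenotypeRegion(recs2, Region("1", 1, 1000),
                             femalePmap(c("s1", "s2")))
  expect_equal(cs2@sites$pos, 70L)
  expect_true(is.na(cs2@A1[2, 1]))
})

test_that("records contradicting the ploidy map are rejected by name", {
  xmap <- scaledXRegionMap(100)
  sexes <- c(s1 = "male")
  nonpar <- 500000L
  recs <- recRow("s1", nonpar, contig = "X", a1 = 0L, a2 = 1L)
  expect_error(
    jointGenotypeRegion(recs, Region("X", 1, scaledXLength(100)),
                        PloidyMap(sexes, xmap, "TWO_PAR"),
                        category = "chrX"),
    "ploidy-conflict.*s1.*500000")
})

test_that("overlap reconciliation keeps concordant calls and removes the rest", {
  mk <- function(ad2 = "0,20") rbind(
    recRow("s1", 100, a1 = 0L, a2 = 1L),
    recRow("s2", 100, a1 = 1L, a2 = 1L, ad = ad2),
    recRow("s1", 900, a1 = 1L, a2 = 1L),
    recRow("s2", 900, a1 = 0L, a2 = 0L))
  pm <- femalePmap(c("s1", "s2"))
  csA <- jointGenotypeRegion(mk(), Region("1", 1, 1000), pm)
  csB <- jointGenotypeRegion(mk(), Region("1", 1, 1000), pm)
  ov <- Region("1", 1, 1000)
  r <- reconcileOverlaps(csA, csB, ov)
  expect_equal(nrow(r$report), 0)
  expect_equal(nSites(r$kept), 2)

  # same position, different alt allele -> removed and reported
  csB2 <- jointGenotypeRegion(
    rbind(recRow("s1", 100, alt = "C", a1 = 0L, a2 = 1L),
          recRow("s2", 100, alt = "C", a1 = 1L, a2 = 1L),
          recRow("s1", 900, a1 = 1L, a2 = 1L),
          recRow("s2", 900, a1 = 0L, a2 = 0L)),
    Region("1", 1, 1000), pm)
  r2 <- reconcileOverlaps(csA, csB2, ov)
  expect_equal(r2$report$pos, 100L)
  expect_equal(r2$report$reason, "allele_mismatch")
  expect_equal(r$kept@sites$pos[r$kept@sites$pos != 100], 900L)

  # single-chunk-only call inside the overlap is discordant too
  csB3 <- callsetSubset(csB, 2)
  r3 <- reconcileOverlaps(csA, csB3, ov)
  expect_equal(r3$report$reason, "chunk_only_A")
  expect_equal(nSites(r3$kept), 1)

  # overlap must be contained in the declared chunk regions
  expect_error(reconcileOverlaps(csA, csB, Region("1", 500, 1500),
                                 regionA = Region("1", 1, 1000)),
               "parameter error")
})

test_that("chunked execution equals the single pass on identical input", {
  spec <- cohortSpec(nSamples = 25, nSitesPerContig = 600,
                     contigPlan = data.frame(name = "1",
                                             category = "autosome",
                                             length = 2e6), seed = 21)
  tr <- simulateTruth(spec)
  recs <- data.table::rbindlist(cohortRecords(tr))
  pm <- PloidyMap(truthSexes(tr), spec@xmap)
  single <- jointGenotypeRegion(recs, Region("1", 1, 2e6), pm)
  ch <- runChunked(recs, "1", 2e6, pm, chunkSize = 5e5, overlap = 1000)
  expect_equal(ch$discordantCount, 0)
  expect_identical(ch$callset@sites, single@sites)
  expect_identical(ch$callset@A1, single@A1)
  expect_identical(ch$callset@A2, single@A2)

  # one-chunk contig degenerates to the plain region call
  one <- runChunked(recs, "1", 2e6, pm, chunkSize = 3e6, overlap = 1000)
  expect_identical(one$callset@sites, single@sites)

  # a genotype perturbed in one chunk's input is removed and reported:
  # pick a variant site and size the chunks so it falls in the first
  # overlap zone [chunkSize - 999, chunkSize]
  target <- single@sites$pos[which.min(abs(single@sites$pos - 1e6))]
  perturb <- function(k, region, records) {
    if (k != 2) return(records)
    r <- data.table::copy(records)
    hit <- which(r$pos == target)
    r$a1[hit] <- 1L - r$a1[hit]
    r
  }
  chp <- runChunked(recs, "1", 2e6, pm, chunkSize = target + 500,
                    overlap = 1000, chunkInput = perturb)
  expect_true(target %in% chp$report$pos)
  expect_false(target %in% chp$callset@sites$pos)
})

test_that("site annotations match their closed forms", {
  # strand-balanced site: Fisher p = 1, FS = 0
  recs <- rbind(recRow("s1", 10, a1 = 0L, a2 = 1L, ad = "10,10",
                       adf = "5,5", adr = "5,5"),
                recRow("s2", 10, a1 = 0L, a2 = 0L, ad = "20,0",
                       adf = "10,0", adr = "10,0"))
  cs <- jointGenotypeRegion(recs, Region("1", 1, 100),
                            femalePmap(c("s1", "s2")))
  ann <- computeSiteAnnotations(cs)
  expect_equal(ann$fs, 0)
  expect_equal(ann$dp, 40)
  # all four pooled counts equal after +1 -> SOR = ln 2
  expect_equal(ann$sor,
               log((16 * 6) / (16 * 6) + 1) + log(1) - log(1))
  expect_equal(ann$sor, log(2))
  # QUAL proxy: only the carrier contributes, capped at 99
  expect_equal(cs@sites$qual, 30)
  expect_equal(ann$qd, 30 / 20)

  # genotype counts exactly at HWE proportions -> inbreeding 0
  recs2 <- rbind(recRow("s1", 10, a1 = 0L, a2 = 0L),
                 recRow("s2", 10, a1 = 0L, a2 = 1L),
                 recRow("s3", 10, a1 = 1L, a2 = 0L),
                 recRow("s4", 10, a1 = 1L, a2 = 1L))
  cs2 <- jointGenotypeRegion(recs2, Region("1", 1, 100),
                             femalePmap(paste0("s", 1:4)))
  ann2 <- computeSiteAnnotations(cs2)
  expect_equal(ann2$inbreeding, 0)
  expect_equal(ann2$hetCount, 2)
  expect_equal(ann2$homAltCount, 1)
})

test_that("FS matches the enumeration oracle on random tables", {
  set.seed(4)
  for (i in 1:100) {
    t <- rpois(4, 6)
    p <- fisherStrandP(t[1], t[2], t[3], t[4])
    expect_equal(p, fisherOracleP(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-12)
  }
})

test_that("hard filters follow comparator semantics and re-check", {
  spec <- cohortSpec(nSamples = 30, nSitesPerContig = 1000,
                     contigPlan = data.frame(name = "1",
                                             category = "autosome",
                                             length = 2e6), seed = 23)
  tr <- simulateTruth(spec)
  cs <- jointGenotypeRegion(data.table::rbindlist(cohortRecords(tr)),
                            Region("1", 1, 2e6),
                            PloidyMap(truthSexes(tr), spec@xmap))
  ann <- computeSiteAnnotations(cs)
  # empty threshold set: everything PASSes
  expect_true(all(applyHardFilters(cs, ann) == "PASS"))
  rules <- list(list(annotation = "fs", max = 3),
                list(annotation = "qd", min = 0.5))
  st <- applyHardFilters(cs, ann, snvRules = rules)
  # independent brute-force re-evaluation
  redo <- ifelse(!is.na(ann$fs) & ann$fs > 3, "FS", "PASS")
  redo <- ifelse(!is.na(ann$qd) & ann$qd < 0.5,
                 ifelse(redo == "PASS", "QD", paste0(redo, ";QD")), redo)
  expect_identical(st, redo)
  expect_gt(sum(st != "PASS"), 0)
  expect_error(applyHardFilters(cs, ann,
                                snvRules = list(list(annotation = "mq",
                                                     max = 40))),
               "config error")
})

test_that("AN accounting follows ploidy and call status", {
  # autosomal: 3 called of 5 -> AN 6
  recs <- data.table::rbindlist(lapply(1:3, function(i)
    recRow(paste0("s", i), 10, a1 = 1L, a2 = 0L)))
  cs <- jointGenotypeRegion(recs, Region("1", 1, 100),
                            femalePmap(paste0("s", 1:5)))
  p <- panelEntries(computeFrequencies(cs))
  expect_equal(p$an, 6L)
  expect_equal(p$ac, 3L)

  # X: 3 females + 2 males -> non-PAR AN 8, PAR1 AN 10
  xmap <- scaledXRegionMap(100)
  sexes <- c(f1 = "female", f2 = "female", f3 = "female",
             m1 = "male", m2 = "male")
  nonpar <- 500000L
  par1 <- 700L  # scaled PAR1 spans 601..26996
  mkx <- function(id, pos, hap) recRow(id, pos, contig = "X",
                                       a1 = 1L,
                                       a2 = if (hap) NA_integer_ else 0L,
                                       ploidy = if (hap) 1L else 2L)
  recs2 <- data.table::rbindlist(c(
    lapply(c("f1", "f2", "f3"), mkx, pos = nonpar, hap = FALSE),
    lapply(c("m1", "m2"), mkx, pos = nonpar, hap = TRUE),
    lapply(names(sexes), mkx, pos = par1, hap = FALSE)))
  csx <- jointGenotypeRegion(recs2, Region("X", 1, scaledXLength(100)),
                             PloidyMap(sexes, xmap, "TWO_PAR"),
                             category = "chrX")
  px <- panelEntries(computeFrequencies(csx))
  expect_equal(px$an[px$pos == par1], 10L)
  expect_equal(px$an[px$pos == nonpar], 8L)
})

test_that("Ts/Tv counting is per-ALT with an undefined zero-denominator", {
  mkpanel <- function(ref, alt) {
    e <- data.frame(contig = "1", pos = seq_along(ref) * 10L, ref = ref,
                    alt = alt, altIndex = 1L, ac = 1L, an = 10L, af = 0.1,
                    multiallelic = FALSE, filter = "PASS",
                    stringsAsFactors = FALSE)
    new("FrequencyPanel", entries = e, nSamples = 5)
  }
  r <- tsTvPanel(mkpanel(c("A", "C", "A"), c("G", "T", "C")))
  expect_equal(r$ratio, 2)
  r2 <- tsTvPanel(mkpanel("A", "G"))
  expect_true(is.na(r2$ratio))
  # multiallelic A -> (G,T): one transition plus one transversion
  e3 <- data.frame(contig = "1", pos = 10L, ref = "A", alt = c("G", "T"),
                   altIndex = 1:2, ac = 1L, an = 10L, af = 0.1,
                   multiallelic = TRUE, filter = "PASS",
                   stringsAsFactors = FALSE)
  r3 <- tsTvPanel(new("FrequencyPanel", entries = e3, nSamples = 5))
  expect_equal(c(r3$ts, r3$tv, r3$ratio), c(1, 1, 1))
  # per-sample counting agrees with a brute-force count on a fixture
  recs <- rbind(recRow("s1", 10, ref = "A", alt = "G", a1 = 0L, a2 = 1L),
                recRow("s1", 20, ref = "C", alt = "T", a1 = 1L, a2 = 1L),
                recRow("s1", 30, ref = "A", alt = "C", a1 = 0L, a2 = 1L),
                recRow("s2", 30, ref = "A", alt = "C", a1 = 0L, a2 = 0L))
  cs <- jointGenotypeRegion(recs, Region("1", 1, 100),
                            femalePmap(c("s1", "s2")))
  ps <- tsTvPerSample(cs)
  expect_equal(ps$ts[ps$sample == "s1"], 2)
  expect_equal(ps$tv[ps$sample == "s1"], 1)
  expect_equal(ps$ts[ps$sample == "s2"], 0)
})

test_that("mean depth tracks average and align", {
  t1 <- cbind(rep(10, 50), rep(10, 50))
  t2 <- cbind(rep(20, 50), rep(20, 50))
  md <- meanDepthTrack(list(t1, t2))
  expect_true(all(md$all == 15))
  expect_true(all(md$diff == 0))
  expect_error(meanDepthTrack(list(t1, t2[1:10, ])), "alignment error")
})
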