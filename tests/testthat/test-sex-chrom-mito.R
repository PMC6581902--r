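test_that("X region classification honours boundaries and PAR convention", {
  m <- grch37XRegionMap()
  expect_equal(classifyXRegion(60001, m), "PAR1")
  expect_equal(classifyXRegion(60000, m), "NONPAR")
  expect_equal(classifyXRegion(2699520, m), "PAR1")
  expect_equal(classifyXRegion(2699521, m), "NONPAR")
  expect_equal(classifyXRegion(88456802, m, mode = "THREE_PAR"), "XTR")
  expect_equal(classifyXRegion(88456802, m, mode = "TWO_PAR"), "NONPAR")
  expect_equal(classifyXRegion(2699521, m, mode = "TWO_PAR"), "NONPAR")
  expect_equal(classifyXRegion(154931044, m), "PAR2")
  expect_error(classifyXRegion(155270561, m, contigLength = 155270560),
               "range error")
})

test_that("ploidy resolution encodes the sex and region rules", {
  xmap <- scaledXRegionMap(100)
  sexes <- c(f = "female", m = "male")
  pos <- c(700L, 500000L, 900000L, 15500000L %/% 10L)
  reg <- classifyXRegion(pos, xmap, "THREE_PAR")
  pm3 <- PloidyMap(sexes, xmap, "THREE_PAR")
  P3 <- resolvePloidy(pm3, "chrX", pos)
  expect_true(all(P3[1, ] == 2L))               # female diploid everywhere
  expect_equal(P3[2, ], ifelse(reg == "NONPAR", 1L, 2L))
  pm2 <- PloidyMap(sexes, xmap, "TWO_PAR")
  reg2 <- classifyXRegion(pos, xmap, "TWO_PAR")
  expect_equal(resolvePloidy(pm2, "chrX", pos)[2, ],
               ifelse(reg2 == "NONPAR", 1L, 2L))
  expect_true(all(resolvePloidy(pm3, "mito", pos) == 1L))
  expect_true(all(resolvePloidy(pm3, "autosome", pos) == 2L))
})

test_that("dual-convention X panels differ only at the XTR", {
  spec <- cohortSpec(nSamples = 30, nSitesPerContig = 800, errorRate = 0,
                     contigPlan = data.frame(name = "X", category = "chrX",
                                             length = scaledXLength(100)),
                     seed = 3)
  tr <- simulateTruth(spec)
  recs <- data.table::rbindlist(cohortRecords(tr))
  sexes <- truthSexes(tr)
  xp <- buildXPanels(recs, sexes, spec@xmap,
                     contigLength = scaledXLength(100))
  e2 <- panelEntries(xp$two_par$panel)
  e3 <- panelEntries(xp$three_par$panel)
  inxtr <- classifyXRegion(e2$pos, spec@xmap, "THREE_PAR") == "XTR"
  expect_identical(e2[!inxtr, ], e3[!inxtr, ])
  # AN rises for males inside the XTR under THREE_PAR
  nf <- sum(sexes == "female"); nm <- sum(sexes == "male")
  expect_true(all(e2$an[inxtr] == 2 * nf + nm))
  expect_true(all(e3$an[inxtr] == 2 * (nf + nm)))
  # male XTR heterozygosity survives only under THREE_PAR
  cs3 <- xp$three_par$callset
  males <- match(names(sexes)[sexes == "male"], cs3@samples)
  xtr_sites <- which(classifyXRegion(cs3@sites$pos, spec@xmap,
                                     "THREE_PAR") == "XTR")
  het3 <- sum(cs3@A1[males, xtr_sites] != cs3@A2[males, xtr_sites],
              na.rm = TRUE)
  expect_gt(het3, 0)
  # no haploid context holds a heterozygote in either panel
  for (cs in list(xp$two_par$callset, cs3)) {
    hap <- cs@PLOIDY == 1L
    expect_true(all(is.na(cs@A2[hap])))
  }
})

test_that("female-only cohorts are invariant to the PAR convention", {
  spec <- cohortSpec(nSamples = 12, sexRatio = 1, nSitesPerContig = 300,
                     errorRate = 0,
                     contigPlan = data.frame(name = "X", category = "chrX",
                                             length = scaledXLength(100)),
                     seed = 5)
  tr <- simulateTruth(spec)
  recs <- data.table::rbindlist(cohortRecords(tr))
  xp <- buildXPanels(recs, truthSexes(tr), spec@xmap,
                     contigLength = scaledXLength(100))
  expect_identical(panelEntries(xp$two_par$panel),
                   panelEntries(xp$three_par$panel))
})

test_that("XTR heterozygosity scan localizes the pseudoautosomal signal", {
  spec <- cohortSpec(nSamples = 40, nSitesPerContig = 3000, errorRate = 0,
                     arrayErrorRate = 0, arrayNoCallRate = 0,
                     arrayMarkerFraction = 1,
                     contigPlan = data.frame(name = "X", category = "chrX",
                                             length = scaledXLength(100)),
                     seed = 14)
  tr <- simulateTruth(spec)
  arr <- emitArrayGenotypes(tr)
  scan <- xtrHeterozygosityScan(arr, truthSexes(tr), spec@xmap,
                                windowMarkers = 15)
  expect_equal(max(scan$rate[scan$region == "NONPAR"], na.rm = TRUE), 0)
  for (r in c("PAR1", "XTR", "PAR2"))
    expect_gt(max(scan$rate[grepl(r, scan$region)]), 0)

  # strictly haploid male truth: all rates zero
  spec0 <- cohortSpec(nSamples = 20, nSitesPerContig = 800, errorRate = 0,
                      arrayErrorRate = 0, arrayNoCallRate = 0,
                      arrayMarkerFraction = 1, xtrDiploid = FALSE,
                      contigPlan = data.frame(name = "X",
                                              category = "chrX",
                                              length = scaledXLength(100)),
                      seed = 15)
  tr0 <- simulateTruth(spec0)
  # restrict to markers outside PAR1/PAR2 (their truth is still diploid)
  arr0 <- emitArrayGenotypes(tr0)
  reg <- classifyXRegion(arr0$pos, spec0@xmap, "THREE_PAR")
  scan0 <- xtrHeterozygosityScan(arr0[reg %in% c("NONPAR", "XTR"), ],
                                 truthSexes(tr0), spec0@xmap,
                                 windowMarkers = 15)
  expect_true(all(scan0$rate == 0, na.rm = TRUE))

  # error-induced het rate in a pure non-PAR window matches expectation:
  # a haploid flip reports as hom, so hets arise only via female flips
  e <- 0.02
  spec1 <- cohortSpec(nSamples = 200, sexRatio = 0, nSitesPerContig = 500,
                      errorRate = 0, arrayErrorRate = e,
                      arrayNoCallRate = 0, arrayMarkerFraction = 1,
                      xtrDiploid = FALSE,
                      contigPlan = data.frame(name = "X",
                                              category = "chrX",
                                              length = scaledXLength(100)),
                      seed = 16)
  tr1 <- simulateTruth(spec1)
  arr1 <- emitArrayGenotypes(tr1)
  reg1 <- classifyXRegion(arr1$pos, spec1@xmap, "THREE_PAR")
  scan1 <- xtrHeterozygosityScan(arr1[reg1 == "NONPAR", ],
                                 truthSexes(tr1), spec1@xmap,
                                 windowMarkers = 1e6)
  expect_equal(scan1$rate, 0)
})

test_that("mitochondrial remapping is the stated bijection", {
  expect_equal(mtRemap(1, 16569, 10000), 10001)
  expect_equal(mtRemap(16569 - 10000 + 1, 16569, 10000), 1)
  L <- 2000; sh <- 700
  all <- mtRemap(1:L, L, sh)
  expect_setequal(all, 1:L)
  expect_equal(mtUnmap(all, L, sh), 1:L)
  expect_error(mtRemap(0, L, sh), "range error")
  expect_error(mtRemap(1, L, L), "shift")
})

test_that("the merged MT panel is edge-aware and agreement-stable", {
  spec <- cohortSpec(nSamples = 20, nSitesPerContig = 300, errorRate = 0,
                     contigPlan = data.frame(name = "MT",
                                             category = "mito",
                                             length = 16569), seed = 8)
  tr <- simulateTruth(spec)
  ml <- mtLinearizedRecords(tr, edgeDropout = 0)
  res <- callMtPanel(ml$primary, ml$shifted, ml$L, ml$shift,
                     edgeMargin = 300)
  # identical call sets on both linearizations: merged equals primary
  sexes <- stats::setNames(rep("female", 20), truthSamples(tr)$id)
  prim <- jointGenotypeRegion(ml$primary, Region("MT", 1, ml$L),
                              PloidyMap(sexes), category = "mito",
                              samples = truthSamples(tr)$id)
  expect_identical(res$callset@sites, prim@sites)
  expect_identical(res$callset@A1, prim@A1)

  # an edge-zone variant present only in the shifted set is recovered
  ml2 <- mtLinearizedRecords(tr, edgeDropout = 100)
  res2 <- callMtPanel(ml2$primary, ml2$shifted, ml2$L, ml2$shift,
                      edgeMargin = 300)
  edge_sites <- prim@sites$pos[prim@sites$pos <= 100 |
                                 prim@sites$pos > ml$L - 100]
  expect_gt(length(edge_sites), 0)
  expect_true(all(edge_sites %in% res2$callset@sites$pos))
  expect_identical(res2$callset@sites$pos, prim@sites$pos)

  # diploid MT genotype is a ploidy conflict
  bad <- data.table::copy(ml$primary)
  bad$ploidy[1] <- 2L
  expect_error(callMtPanel(bad, ml$shifted, ml$L, ml$shift),
               "ploidy-conflict")
})
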