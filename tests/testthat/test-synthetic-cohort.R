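test_that("identical specs produce byte-identical cohorts and files", {
  spec <- cohortSpec(nSamples = 12, nSitesPerContig = 80, seed = 99)
  t1 <- simulateTruth(spec)
  t2 <- simulateTruth(spec)
  expect_identical(t1@A1, t2@A1)
  expect_identical(t1@A2, t2@A2)
  expect_identical(truthSamples(t1), truthSamples(t2))
  d1 <- tempfile(); d2 <- tempfile()
  emitSampleVcfs(t1, d1)
  emitSampleVcfs(t2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("duplicates are exact copies and haploid contexts never het", {
  spec <- cohortSpec(nSamples = 16, nSitesPerContig = 150, errorRate = 0,
                     relativePlan = data.frame(relationship = "duplicate",
                                               count = 1), seed = 4)
  tr <- simulateTruth(spec)
  sm <- truthSamples(tr)
  dup <- sm$id[sm$role == "duplicate"]
  src <- sm$relatedTo[sm$role == "duplicate"]
  i <- match(dup, sm$id); j <- match(src, sm$id)
  expect_identical(tr@A1[i, ], tr@A1[j, ])
  expect_identical(tr@A2[i, ], tr@A2[j, ])
  # ploidy conservation: no haploid cell carries two alleles
  st <- truthSites(tr)
  male <- sm$sex == "male"
  xhap <- st$category == "chrX" & !st$maleDiploid
  expect_true(all(is.na(tr@A2[male, xhap])))
  expect_true(all(is.na(tr@A2[, st$category == "mito"])))
  # and the generated records agree
  recs <- data.table::rbindlist(cohortRecords(tr))
  mt <- recs[recs$contig == "MT"]
  expect_true(all(mt$ploidy == 1L))
  expect_true(all(is.na(mt$a2)))
})

test_that("parent-offspring trios are Mendelian at zero error", {
  spec <- cohortSpec(nSamples = 14, nSitesPerContig = 400, errorRate = 0,
                     relativePlan = data.frame(
                       relationship = "parent_offspring", count = 1),
                     seed = 6)
  tr <- simulateTruth(spec)
  sm <- truthSamples(tr)
  child <- sm$id[sm$role == "child"]
  par <- strsplit(sm$relatedTo[sm$role == "child"], ",")[[1]]
  expect_equal(mendelianViolations(tr, child, par[1], par[2]), 0L)
})

test_that("relative plans larger than the cohort are a spec error", {
  spec <- cohortSpec(nSamples = 3, nSitesPerContig = 100,
                     relativePlan = data.frame(
                       relationship = "parent_offspring", count = 2),
                     seed = 1)
  expect_error(simulateTruth(spec), "spec error")
})

test_that("zero error reproduces truth; flip rate matches the model", {
  spec0 <- cohortSpec(nSamples = 10, nSitesPerContig = 200, errorRate = 0,
                      dropoutRate = 0, seed = 8)
  tr0 <- simulateTruth(spec0)
  recs <- data.table::rbindlist(cohortRecords(tr0))
  truthdt <- data.table::data.table(
    sample = rep(truthSamples(tr0)$id, each = nrow(truthSites(tr0))),
    pos = rep(truthSites(tr0)$pos, nrow(truthSamples(tr0))),
    contig = rep(truthSites(tr0)$contig, nrow(truthSamples(tr0))),
    ta1 = as.vector(t(tr0@A1)), ta2 = as.vector(t(tr0@A2)))
  m <- merge(recs, truthdt, by = c("sample", "contig", "pos"))
  expect_equal(m$a1, m$ta1)
  expect_equal(m$a2, m$ta2)
  # PL minimum is 0 for every record
  plmin <- vapply(strsplit(recs$pl, ","),
                  function(v) min(as.numeric(v)), numeric(1))
  expect_true(all(plmin == 0))

  # empirical flip rate within 3 binomial SD at 10,000 genotypes
  e <- 0.02
  spec1 <- cohortSpec(nSamples = 50, nSitesPerContig = 200, errorRate = e,
                      contigPlan = data.frame(name = "1",
                                              category = "autosome",
                                              length = 1e6), seed = 8)
  tr1 <- simulateTruth(spec1)
  recs1 <- data.table::rbindlist(cohortRecords(tr1))
  truth1 <- data.table::data.table(
    sample = rep(truthSamples(tr1)$id, each = nrow(truthSites(tr1))),
    pos = rep(truthSites(tr1)$pos, nrow(truthSamples(tr1))),
    ta1 = as.vector(t(tr1@A1)), ta2 = as.vector(t(tr1@A2)))
  m1 <- merge(recs1, truth1, by = c("sample", "pos"))
  flipped <- (m1$a1 + m1$a2) != (m1$ta1 + m1$ta2)
  n <- nrow(m1)
  expect_gt(n, 9999)
  expect_lt(abs(mean(flipped) - e), 3 * sqrt(e * (1 - e) / n))
})

test_that("array table obeys its no-call and lossless limits", {
  # lossless case: equals truth restricted to markers
  spec <- cohortSpec(nSamples = 15, nSitesPerContig = 200, errorRate = 0,
                     arrayErrorRate = 0, arrayNoCallRate = 0,
                     arrayMarkerFraction = 0.5, seed = 13)
  tr <- simulateTruth(spec)
  arr <- emitArrayGenotypes(tr)
  st <- truthSites(tr)
  midx <- match(paste(arr$contig, arr$pos), paste(st$contig, st$pos))
  ids <- truthSamples(tr)$id
  for (i in seq_along(ids)) {
    hap <- is.na(tr@A2[i, midx])
    dose <- ifelse(hap, tr@A1[i, midx] * 2L,
                   tr@A1[i, midx] + tr@A2[i, midx])
    expect_identical(arr[[ids[i]]], c("0/0", "0/1", "1/1")[dose + 1L])
  }

  # degenerate no-call
  spec2 <- cohortSpec(nSamples = 5, nSitesPerContig = 50,
                      arrayNoCallRate = 1, seed = 13)
  arr2 <- emitArrayGenotypes(simulateTruth(spec2))
  g <- as.matrix(arr2[, truthSamples(simulateTruth(spec2))$id,
                      with = FALSE])
  expect_true(all(g == "NoCall"))

  # no-call fraction within 3 SD at >= 10,000 entries
  nc <- 0.05
  spec3 <- cohortSpec(nSamples = 60, nSitesPerContig = 400,
                      arrayNoCallRate = nc, arrayMarkerFraction = 1,
                      contigPlan = data.frame(name = "1",
                                              category = "autosome",
                                              length = 1e6), seed = 14)
  arr3 <- emitArrayGenotypes(simulateTruth(spec3))
  g3 <- as.matrix(arr3[, -(1:4)])
  expect_gt(length(g3), 9999)
  expect_lt(abs(mean(g3 == "NoCall") - nc),
            3 * sqrt(nc * (1 - nc) / length(g3)))
})

test_that("depth tracks respect the MAPQ mixture", {
  # no multimapping: the two tracks are identical
  spec0 <- cohortSpec(nSamples = 4, nSitesPerContig = 30,
                      mapq0Fraction = 0, repeatFraction = 0,
                      depthTrackBases = 2000, seed = 5)
  dt0 <- emitDepthTracks(simulateTruth(spec0))
  for (t in dt0$tracks) expect_identical(t[, 1], t[, 2])

  # total loss on repeat bases
  spec1 <- cohortSpec(nSamples = 4, nSitesPerContig = 30,
                      mapq0Fraction = 0, mapq0Repeat = 1,
                      repeatFraction = 0.2, depthTrackBases = 2000,
                      seed = 5)
  dt1 <- emitDepthTracks(simulateTruth(spec1))
  for (t in dt1$tracks) {
    expect_true(all(t[dt1$repeatMask, 2] == 0))
    expect_true(all(t[, 1] >= t[, 2]))
  }
  # difference elevated precisely on the designated repeat set
  md <- meanDepthTrack(dt1$tracks)
  expect_gt(mean(md$diff[dt1$repeatMask]),
            mean(md$diff[!dt1$repeatMask]) + 10)
  expect_equal(mean(md$diff[!dt1$repeatMask]), 0)
})

test_that("simulated site frequencies converge to the Beta prior mean", {
  spec <- cohortSpec(nSamples = 2000, nSitesPerContig = 1000, afAlpha = 1,
                     afBeta = 3,
                     contigPlan = data.frame(name = "1",
                                             category = "autosome",
                                             length = 1e6), seed = 17)
  tr <- simulateTruth(spec)
  emp <- colMeans(tr@A1 + tr@A2) / 2
  expect_lt(abs(mean(emp) - 1 / 4), 0.02)
})
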