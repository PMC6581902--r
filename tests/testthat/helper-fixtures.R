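# Shared fixtures and independent oracles, all built in code.

# one record row with sensible defaults
recRow <- function(sample, pos, ref = "A", alt = "G", a1 = 0L, a2 = 0L,
                   ploidy = 2L, dp = 20L, ad = "10,10", adf = "5,5",
                   adr = "5,5", pl = NA_character_, gq = 30,
                   contig = "1") {
  data.table::data.table(sample = sample, contig = contig,
                         pos = as.integer(pos), ref = ref, alt = alt,
                         a1 = a1, a2 = a2, ploidy = ploidy, dp = dp,
                         ad = ad, adf = adf, adr = adr, pl = pl, gq = gq)
}

femalePmap <- function(ids, xmap = NULL, mode = NULL) {
  PloidyMap(stats::setNames(rep("female", length(ids)), ids), xmap, mode)
}

# brute-force Mendelian consistency over autosomal truth genotypes
mendelianViolations <- function(truth, child, father, mother) {
  st <- truthSites(truth)
  ids <- truthSamples(truth)$id
  ci <- match(child, ids); fi <- match(father, ids); mi <- match(mother, ids)
  auto <- which(st$category == "autosome")
  bad <- 0L
  for (j in auto) {
    ca <- c(truth@A1[ci, j], truth@A2[ci, j])
    fa <- c(truth@A1[fi, j], truth@A2[fi, j])
    ma <- c(truth@A1[mi, j], truth@A2[mi, j])
    ok <- (ca[1] %in% fa && ca[2] %in% ma) ||
      (ca[2] %in% fa && ca[1] %in% ma)
    if (!ok) bad <- bad + 1L
  }
  bad
}

# exhaustive-enumeration Hardy-Weinberg oracle: probability of each genotype
# configuration with the observed allele counts by counting arrangements
hweOracleEnum <- function(a, b, c) {
  n <- a + b + c
  nA <- 2 * a + b
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  w <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  sum(pr[pr <= pr[match(b, hs)] * (1 + 1e-12)])
}

# two-sided Fisher oracle by full table enumeration with lchoose arithmetic
fisherOracleP <- function(rf, rr, af, ar) {
  r1 <- rf + rr; r2 <- af + ar; c1 <- rf + af
  if (r1 + r2 == 0) return(1)
  supp <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(r1 + r2, c1)
  pr <- exp(lp)
  pobs <- pr[match(rf, supp)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# tiny deterministic cohort used by several files
smallCohort <- function(...) {
  spec <- cohortSpec(nSamples = 20, nSitesPerContig = 120, seed = 42, ...)
  simulateTruth(spec)
}
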