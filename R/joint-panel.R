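# Joint genotype aggregation across samples, chunked execution with overlap
# reconciliation, site annotations, hard filters, ploidy-aware AC/AN/AF,
# Ts/Tv and accessibility tracks.

# ---- call-set plumbing -----------------------------------------------------

#' Subset or concatenate call sets
#'
#' `callsetSubset` keeps the given site columns; `callsetBind` concatenates
#' call sets over the same samples and re-sorts by (contig, pos).
#'
#' @param cs a [VariantCallSet].
#' @param idx site indices to keep.
#' @export
callsetSubset <- function(cs, idx) {
  sites <- cs@sites[idx, , drop = FALSE]
  rownames(sites) <- NULL
  new("VariantCallSet", samples = cs@samples,
      sites = sites,
      A1 = cs@A1[, idx, drop = FALSE], A2 = cs@A2[, idx, drop = FALSE],
      DP = cs@DP[, idx, drop = FALSE],
      PLOIDY = cs@PLOIDY[, idx, drop = FALSE])
}

#' @rdname callsetSubset
#' @param csList list of [VariantCallSet]s sharing the same sample vector.
#' @export
callsetBind <- function(csList) {
  csList <- Filter(function(x) nrow(x@sites) > 0 || TRUE, csList)
  smp <- csList[[1]]@samples
  for (cs in csList)
    if (!identical(cs@samples, smp)) stop("sample vectors differ")
  sites <- do.call(rbind, lapply(csList, function(x) x@sites))
  rownames(sites) <- NULL
  bindm <- function(m) do.call(cbind, lapply(csList, function(x) slot(x, m)))
  out <- new("VariantCallSet", samples = smp, sites = sites,
             A1 = bindm("A1"), A2 = bindm("A2"), DP = bindm("DP"),
             PLOIDY = bindm("PLOIDY"))
  ord <- order(match(out@sites$contig, unique(out@sites$contig)),
               out@sites$pos)
  callsetSubset(out, ord)
}

empty_sites <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), nalt = integer(0), qual = numeric(0),
             reffwd = numeric(0), refrev = numeric(0), altfwd = numeric(0),
             altrev = numeric(0), multiallelic = logical(0),
             stringsAsFactors = FALSE)
}

empty_callset <- function(samples) {
  z <- matrix(NA_integer_, length(samples), 0)
  new("VariantCallSet", samples = samples, sites = empty_sites(),
      A1 = z, A2 = z, DP = z, PLOIDY = z)
}

# ---- joint genotyping ------------------------------------------------------

#' Joint genotype aggregation over one region
#'
#' Combines coordinate-sorted per-sample records into cohort-level variant
#' sites: a site is emitted at every position where at least one sample's
#' genotype carries an alternative allele. Allele lists are merged across
#' samples into one ordered ALT list (descending pooled allele depth, ties
#' broken by allele string) and each sample's genotype is re-expressed in the
#' merged indexing; samples without a record at a site are no-calls. The
#' aggregation trusts each record's stored genotype (the likelihood argmax of
#' its own PL vector, ties toward the lower genotype index at read time); it
#' does not realign or re-assemble.
#'
#' The site QUAL proxy is the sum, over samples carrying an alternative
#' allele, of the gap between their two smallest phred likelihoods, capped at
#' 99 per sample.
#'
#' @param records combined record table (all samples, [readSampleVcf()]
#'   schema).
#' @param region the [Region] to genotype.
#' @param pmap a [PloidyMap] resolving expected ploidy per (sample,
#'   position).
#' @param category contig category ("autosome", "chrX" or "mito").
#' @param samples sample ids fixing matrix row order (default: the ploidy
#'   map's sample order).
#' @return a [VariantCallSet].
#' @export
jointGenotypeRegion <- function(records, region, pmap,
                                category = "autosome", samples = NULL) {
  if (is.null(samples)) samples <- names(pmap@sexes)
  rec <- data.table::as.data.table(records)
  rec <- rec[rec$contig == region@contig & rec$pos >= region@start &
               rec$pos <= region@end]
  if (nrow(rec) == 0) return(empty_callset(samples))
  unknown <- setdiff(unique(rec$sample), samples)
  if (length(unknown))
    stop(sprintf("records for unknown sample(s): %s",
                 paste(unknown, collapse = ",")))

  carrier <- (!is.na(rec$a1) & rec$a1 > 0) | (!is.na(rec$a2) & rec$a2 > 0)
  vp <- sort(unique(rec$pos[carrier]))
  if (length(vp) == 0) return(empty_callset(samples))
  rec <- rec[rec$pos %in% vp]
  carrier <- (!is.na(rec$a1) & rec$a1 > 0) | (!is.na(rec$a2) & rec$a2 > 0)

  # ploidy contract: a called record must match the resolved ploidy
  called <- !is.na(rec$ploidy)
  expP <- resolvePloidy(pmap, category, rec$pos)
  expv <- expP[cbind(match(rec$sample, samples), seq_len(nrow(rec)))]
  bad <- which(called & rec$ploidy != expv)
  if (length(bad))
    stop(sprintf("ploidy-conflict error: sample %s at %s:%d has ploidy %d, expected %d",
                 rec$sample[bad[1]], rec$contig[bad[1]], rec$pos[bad[1]],
                 rec$ploidy[bad[1]], expv[bad[1]]))

  # per-record allele depths / strand counts, ragged-parsed once
  maxalt <- max(ifelse(rec$alt == "", 0L,
                       lengths(regmatches(rec$alt, gregexpr(",", rec$alt))) + 1L))
  nsplit <- maxalt + 1L
  numcols <- function(x) {
    cols <- data.table::tstrsplit(x, ",", fixed = TRUE)
    length(cols) <- nsplit
    m <- matrix(NA_real_, nrow(rec), nsplit)
    for (j in seq_along(cols))
      if (!is.null(cols[[j]]))
        m[, j] <- suppressWarnings(as.numeric(cols[[j]]))
    m
  }
  AD <- numcols(rec$ad)
  ADF <- numcols(rec$adf)
  ADR <- numcols(rec$adr)
  altmat <- {
    cols <- data.table::tstrsplit(ifelse(rec$alt == "", NA_character_,
                                         rec$alt), ",", fixed = TRUE)
    length(cols) <- max(maxalt, 1L)
    m <- matrix(NA_character_, nrow(rec), max(maxalt, 1L))
    for (j in seq_along(cols)) if (!is.null(cols[[j]])) m[, j] <- cols[[j]]
    m
  }

  # pooled depth per carried allele -> merged ALT order per position
  carried_rows <- function(acol) {
    i <- which(!is.na(acol) & acol > 0)
    if (!length(i)) return(NULL)
    data.table::data.table(pos = rec$pos[i],
                           allele = altmat[cbind(i, acol[i])],
                           ad = AD[cbind(i, acol[i] + 1L)])
  }
  car <- data.table::rbindlist(list(carried_rows(rec$a1),
                                    carried_rows(rec$a2)))
  car <- car[!is.na(car$allele)]
  ad <- allele <- pos <- NULL # data.table NSE
  pooled <- car[, list(pooledAD = sum(ad, na.rm = TRUE)),
                by = c("pos", "allele")]
  data.table::setorder(pooled, pos, -pooledAD, allele)
  pooled[, `:=`(mergedIdx = seq_len(.N)), by = "pos"]

  sitealt <- pooled[, list(alt = paste(allele, collapse = ","),
                           nalt = .N), by = "pos"]
  data.table::setorder(sitealt, pos)
  stopifnot(identical(sitealt$pos, vp))

  # reference allele per site must agree across samples
  refs <- rec[, list(ref = unique(ref)), by = "pos"]
  if (nrow(refs) != length(vp))
    stop(sprintf("reference allele mismatch at position %s",
                 refs$pos[duplicated(refs$pos)][1]))
  data.table::setorder(refs, pos)

  # re-express genotypes in merged indexing
  amap <- stats::setNames(pooled$mergedIdx,
                          paste(pooled$pos, pooled$allele, sep = "\r"))
  reindex <- function(acol) {
    out <- acol
    i <- which(!is.na(acol) & acol > 0)
    if (length(i))
      out[i] <- as.integer(amap[paste(rec$pos[i], altmat[cbind(i, acol[i])],
                                      sep = "\r")])
    out
  }
  a1new <- reindex(rec$a1)
  a2new <- reindex(rec$a2)

  ns <- length(samples)
  nv <- length(vp)
  si <- match(rec$sample, samples)
  vi <- match(rec$pos, vp)
  A1 <- A2 <- DPm <- matrix(NA_integer_, ns, nv)
  ij <- cbind(si, vi)
  A1[ij] <- as.integer(a1new)
  A2[ij] <- as.integer(a2new)
  DPm[ij] <- as.integer(rec$dp)

  # pooled strand counts (ref vs all ALTs) and QUAL proxy
  refF <- rowsum_by(ADF[, 1], vi, nv)
  refR <- rowsum_by(ADR[, 1], vi, nv)
  altF <- rowsum_by(rowSums(ADF[, -1, drop = FALSE], na.rm = TRUE), vi, nv)
  altR <- rowsum_by(rowSums(ADR[, -1, drop = FALSE], na.rm = TRUE), vi, nv)
  qual <- rowsum_by(ifelse(carrier, pmin(rec$gq, 99), 0), vi, nv)

  sites <- data.frame(contig = region@contig, pos = vp, ref = refs$ref,
                      alt = sitealt$alt, nalt = sitealt$nalt, qual = qual,
                      reffwd = refF, refrev = refR, altfwd = altF,
                      altrev = altR, multiallelic = sitealt$nalt > 1,
                      stringsAsFactors = FALSE)
  new("VariantCallSet", samples = samples, sites = sites, A1 = A1, A2 = A2,
      DP = DPm, PLOIDY = resolvePloidy(pmap, category, vp))
}

rowsum_by <- function(x, group, n) {
  x[is.na(x)] <- 0
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# ---- overlap reconciliation ------------------------------------------------

#' Reconcile variant calls in a chunk overlap
#'
#' Inside the overlap region, a position present in both chunks with
#' identical (ref, ALT list, full per-sample genotype vector) is kept once;
#' a position present in both but differing in any of those, or present in
#' only one chunk, is treated as discordant, excluded, and listed in the
#' report. Sites outside the overlap pass through untouched.
#'
#' @param csA,csB [VariantCallSet]s from adjacent chunks (same samples).
#' @param overlap the overlap [Region].
#' @param regionA,regionB optional chunk [Region]s; when given, the overlap
#'   must be contained in both.
#' @return list with `kept` (merged [VariantCallSet]) and `report`
#'   (data.frame of removed variants: contig, pos, ref, altA, altB, reason).
#' @export
reconcileOverlaps <- function(csA, csB, overlap, regionA = NULL,
                              regionB = NULL) {
  contained <- function(rg) is.null(rg) ||
    (overlap@start >= rg@start && overlap@end <= rg@end)
  if (!contained(regionA) || !contained(regionB))
    stop("parameter error: overlap region not contained in both chunks")
  if (!identical(csA@samples, csB@samples)) stop("sample vectors differ")
  inov <- function(cs) cs@sites$pos >= overlap@start &
    cs@sites$pos <= overlap@end & cs@sites$contig == overlap@contig
  ia <- which(inov(csA))
  ib <- which(inov(csB))
  posA <- csA@sites$pos[ia]
  posB <- csB@sites$pos[ib]
  common <- intersect(posA, posB)
  rows <- list()
  keep_a <- integer(0)
  geno_equal <- function(i, j) {
    identical(csA@A1[, i], csB@A1[, j]) && identical(csA@A2[, i], csB@A2[, j])
  }
  for (p in common) {
    i <- ia[match(p, posA)]
    j <- ib[match(p, posB)]
    if (csA@sites$ref[i] != csB@sites$ref[j] ||
        csA@sites$alt[i] != csB@sites$alt[j]) {
      rows[[length(rows) + 1]] <- data.frame(
        contig = overlap@contig, pos = p, ref = csA@sites$ref[i],
        altA = csA@sites$alt[i], altB = csB@sites$alt[j],
        reason = "allele_mismatch", stringsAsFactors = FALSE)
    } else if (!geno_equal(i, j)) {
      rows[[length(rows) + 1]] <- data.frame(
        contig = overlap@contig, pos = p, ref = csA@sites$ref[i],
        altA = csA@sites$alt[i], altB = csB@sites$alt[j],
        reason = "genotype_mismatch", stringsAsFactors = FALSE)
    } else {
      keep_a <- c(keep_a, i)
    }
  }
  only <- function(cs, idx, posv, other, lab) {
    sel <- idx[!posv %in% other]
    if (!length(sel)) return(NULL)
    data.frame(contig = overlap@contig, pos = cs@sites$pos[sel],
               ref = cs@sites$ref[sel], altA = NA_character_,
               altB = NA_character_, reason = lab, stringsAsFactors = FALSE)
  }
  oa <- only(csA, ia, posA, posB, "chunk_only_A")
  ob <- only(csB, ib, posB, posA, "chunk_only_B")
  report <- rbind(do.call(rbind, rows), oa, ob)
  if (is.null(report))
    report <- data.frame(contig = character(0), pos = integer(0),
                         ref = character(0), altA = character(0),
                         altB = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  report <- report[order(report$pos), , drop = FALSE]
  rownames(report) <- NULL
  outA <- setdiff(which(!inov(csA)), integer(0))
  outB <- which(!inov(csB))
  # outside-overlap duplicates (possible when chaining) resolve to A's copy
  outB <- outB[!csB@sites$pos[outB] %in% csA@sites$pos[outA]]
  kept <- callsetBind(list(callsetSubset(csA, sort(c(outA, keep_a))),
                           callsetSubset(csB, outB)))
  list(kept = kept, report = report)
}

#' Chunked joint genotyping over a whole contig
#'
#' Partitions the contig with [partitionContig()], joint-genotypes each chunk
#' across all samples, then concatenates adjacent chunks with
#' [reconcileOverlaps()], removing and reporting any call that is not
#' reproduced identically in both copies of an overlap zone. For a
#' deterministic aggregation over identical inputs the result is identical to
#' a single-pass run with an empty report.
#'
#' @param records combined record table for the contig.
#' @param contigName,contigLength contig identity and length.
#' @param pmap a [PloidyMap].
#' @param chunkSize,overlap chunking parameters (defaults 3 Mb / 1 kb).
#' @param category contig category.
#' @param chunkInput optional `function(chunkIndex, region, records)`
#'   returning the record table used for that chunk; intended for overlap
#'   consistency audits (supplying a perturbed copy for one chunk).
#' @return list with `callset`, `report` (removed variants) and
#'   `discordantCount`.
#' @export
runChunked <- function(records, contigName, contigLength, pmap,
                       chunkSize = 3e6, overlap = 1000,
                       category = "autosome", chunkInput = NULL) {
  chunks <- partitionContig(contigLength, chunkSize, overlap)
  css <- vector("list", nrow(chunks))
  for (k in seq_len(nrow(chunks))) {
    rg <- Region(contigName, chunks$start[k], chunks$end[k])
    rk <- if (is.null(chunkInput)) records else
      chunkInput(k, rg, records)
    css[[k]] <- jointGenotypeRegion(rk, rg, pmap, category = category)
  }
  acc <- css[[1]]
  reports <- list()
  for (k in seq_len(nrow(chunks))[-1]) {
    ov <- Region(contigName, chunks$start[k], chunks$end[k - 1])
    res <- reconcileOverlaps(acc, css[[k]], ov,
                             regionB = Region(contigName, chunks$start[k],
                                              chunks$end[k]))
    acc <- res$kept
    reports[[length(reports) + 1]] <- res$report
  }
  report <- if (length(reports)) do.call(rbind, reports) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               altA = character(0), altB = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(acc@sites$pos))
  list(callset = acc, report = report, discordantCount = nrow(report))
}

# ---- site annotations and filters -----------------------------------------

#' Two-sided Fisher exact p for pooled strand counts
#'
#' Exact conditional p-value of the 2x2 table (ref fwd/rev vs alt fwd/rev):
#' the sum of hypergeometric probabilities of tables, with the observed
#' margins, no more probable than the observed one (standard two-sided
#' definition, not mid-p).
#'
#' @param reffwd,refrev,altfwd,altrev strand counts (vectors accepted).
#' @return p-values in (0, 1].
#' @export
fisherStrandP <- function(reffwd, refrev, altfwd, altrev) {
  n <- length(reffwd)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r1 <- reffwd[i] + refrev[i]
    r2 <- altfwd[i] + altrev[i]
    c1 <- reffwd[i] + altfwd[i]
    if (r1 + r2 == 0) { out[i] <- 1; next }
    supp <- max(0, c1 - r2):min(r1, c1)
    d <- stats::dhyper(supp, r1, r2, c1)
    dobs <- d[match(reffwd[i], supp)]
    out[i] <- min(1, sum(d[d <= dobs * (1 + 1e-7)]))
  }
  out
}

#' Compute per-site annotations
#'
#' For every site of a call set computes the filtering annotations: `dp`
#' (total depth over samples), `qd` (QUAL proxy normalized by the depth of
#' samples carrying an alternative allele), `fs` (phred-scaled two-sided
#' Fisher exact strand-bias p on the pooled ref/alt forward/reverse table,
#' floored at 0), `sor` (symmetric odds ratio strand bias on the pooled table
#' with +1 pseudocounts: `ln(R + 1/R) + ln(refRatio) - ln(altRatio)` with `R`
#' the cross ratio and each ratio the min/max of the strand counts), and
#' `inbreeding` (1 - observed het count / expected het count, expectation
#' `2p(1-p)` times the diploid called sample count; NA when no diploid
#' samples are called or the expectation is 0). Also returns `hetCount`
#' (diploid heterozygotes) and `homAltCount` (homozygous or haploid
#' alternative genotypes).
#'
#' @param cs a [VariantCallSet].
#' @return data.frame, one row per site.
#' @export
computeSiteAnnotations <- function(cs) {
  nv <- nrow(cs@sites)
  if (nv == 0)
    return(data.frame(qd = numeric(0), dp = numeric(0), fs = numeric(0),
                      sor = numeric(0), inbreeding = numeric(0),
                      hetCount = integer(0), homAltCount = integer(0)))
  carrier <- (!is.na(cs@A1) & cs@A1 > 0) | (!is.na(cs@A2) & cs@A2 > 0)
  DP0 <- cs@DP
  DP0[is.na(DP0)] <- 0L
  dp <- colSums(DP0)
  dpAlt <- colSums(DP0 * carrier)
  qd <- ifelse(dpAlt > 0, cs@sites$qual / dpAlt, NA_real_)
  p <- fisherStrandP(cs@sites$reffwd, cs@sites$refrev, cs@sites$altfwd,
                     cs@sites$altrev)
  fs <- pmax(0, -10 * log10(p))
  rf <- cs@sites$reffwd + 1
  rr <- cs@sites$refrev + 1
  af <- cs@sites$altfwd + 1
  ar <- cs@sites$altrev + 1
  R <- (rf * ar) / (rr * af)
  sor <- log(R + 1 / R) + log(pmin(rf, rr) / pmax(rf, rr)) -
    log(pmin(af, ar) / pmax(af, ar))
  dip <- cs@PLOIDY == 2L & !is.na(cs@A1)
  het <- dip & cs@A1 != cs@A2
  hetCount <- colSums(het, na.rm = TRUE)
  homAlt <- (!is.na(cs@A1) & cs@A1 > 0) &
    (is.na(cs@A2) & cs@PLOIDY == 1L | (!is.na(cs@A2) & cs@A1 == cs@A2))
  nDip <- colSums(dip)
  altDose <- (cs@A1 > 0) + (cs@A2 > 0)
  altDose[!dip] <- NA
  pAlt <- colSums(altDose, na.rm = TRUE) / (2 * nDip)
  hetExp <- 2 * pAlt * (1 - pAlt) * nDip
  inbreeding <- ifelse(nDip > 0 & hetExp > 0, 1 - hetCount / hetExp,
                       NA_real_)
  data.frame(qd = qd, dp = dp, fs = fs, sor = sor, inbreeding = inbreeding,
             hetCount = hetCount, homAltCount = colSums(homAlt, na.rm = TRUE))
}

#' Apply configurable hard filters to annotated sites
#'
#' A surrogate for mixture-model recalibration: a site PASSes iff every
#' configured threshold for its class (SNV or INDEL) is met. Each rule is a
#' list with `annotation` (one of qd, dp, fs, sor, inbreeding) and `min`
#' and/or `max`. The names of failed annotations are recorded
#' (semicolon-joined) as the filter status. Sites whose annotation is NA are
#' not failed by that rule. Defaults are empty rule sets (everything PASSes).
#'
#' @param cs a [VariantCallSet].
#' @param annotations output of [computeSiteAnnotations()] for `cs`.
#' @param snvRules,indelRules lists of rules, applied to SNV and INDEL sites
#'   independently.
#' @return character vector of per-site filter statuses.
#' @export
applyHardFilters <- function(cs, annotations, snvRules = list(),
                             indelRules = list()) {
  nv <- nrow(cs@sites)
  known <- c("qd", "dp", "fs", "sor", "inbreeding")
  is_snv <- vapply(seq_len(nv), function(i) {
    alts <- strsplit(cs@sites$alt[i], ",", fixed = TRUE)[[1]]
    nchar(cs@sites$ref[i]) == 1 && all(nchar(alts) == 1)
  }, logical(1))
  status <- rep("PASS", nv)
  eval_rules <- function(rules, idx) {
    for (rule in rules) {
      ann <- rule$annotation
      if (!ann %in% known)
        stop(sprintf("config error: unknown annotation '%s'", ann))
      v <- annotations[[ann]][idx]
      fail <- rep(FALSE, length(idx))
      if (!is.null(rule$min)) fail <- fail | (!is.na(v) & v < rule$min)
      if (!is.null(rule$max)) fail <- fail | (!is.na(v) & v > rule$max)
      hit <- idx[fail]
      status[hit] <<- ifelse(status[hit] == "PASS", toupper(ann),
                             paste(status[hit], toupper(ann), sep = ";"))
    }
  }
  eval_rules(snvRules, which(is_snv))
  eval_rules(indelRules, which(!is_snv))
  status
}

# ---- frequencies -----------------------------------------------------------

#' Compute the allele frequency panel from a call set
#'
#' AN at a site is the sum of the resolved ploidies of the called samples
#' (no-calls are excluded); AC counts occurrences of each ALT allele across
#' called genotypes; AF = AC/AN. Multiallelic sites are retained and yield
#' one panel entry per ALT.
#'
#' @param cs a [VariantCallSet] (carries per-sample ploidies resolved at
#'   joint genotyping time).
#' @param filter optional per-site filter status vector (default "PASS").
#' @return a [FrequencyPanel].
#' @export
computeFrequencies <- function(cs, filter = NULL) {
  nv <- nrow(cs@sites)
  if (nv == 0)
    return(new("FrequencyPanel", entries = empty_panel_entries(),
               nSamples = length(cs@samples)))
  if (is.null(filter)) filter <- rep("PASS", nv)
  called <- !is.na(cs@A1)
  bad <- called & cs@PLOIDY == 2L & is.na(cs@A2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("ploidy-conflict error: haploid genotype for sample %s at %s:%d in a diploid context",
                 cs@samples[w[1]], cs@sites$contig[w[2]],
                 cs@sites$pos[w[2]]))
  }
  bad <- cs@PLOIDY == 1L & !is.na(cs@A2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("ploidy-conflict error: diploid genotype for sample %s at %s:%d in a haploid context",
                 cs@samples[w[1]], cs@sites$contig[w[2]],
                 cs@sites$pos[w[2]]))
  }
  an <- colSums(cs@PLOIDY * called)
  maxalt <- max(cs@sites$nalt)
  aclist <- vector("list", maxalt)
  for (k in seq_len(maxalt)) {
    aclist[[k]] <- colSums(cs@A1 == k, na.rm = TRUE) +
      colSums(cs@A2 == k, na.rm = TRUE)
  }
  altsplit <- strsplit(cs@sites$alt, ",", fixed = TRUE)
  rows <- lapply(seq_len(nv), function(i) {
    ks <- seq_len(cs@sites$nalt[i])
    ac <- vapply(ks, function(k) aclist[[k]][i], numeric(1))
    data.frame(contig = cs@sites$contig[i], pos = cs@sites$pos[i],
               ref = cs@sites$ref[i], alt = altsplit[[i]], altIndex = ks,
               ac = as.integer(ac), an = as.integer(an[i]),
               af = ifelse(an[i] > 0, ac / an[i], 0),
               multiallelic = cs@sites$nalt[i] > 1, filter = filter[i],
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  new("FrequencyPanel", entries = entries, nSamples = length(cs@samples))
}

# ---- Ts/Tv -----------------------------------------------------------------

.is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion ratio of a panel
#'
#' Counts each SNV panel entry (per ALT; indels skipped) as a transition
#' (A<->G, C<->T) or transversion. The ratio is NA when there are no
#' transversions.
#'
#' @param panel a [FrequencyPanel].
#' @param byContig if TRUE, one ratio per contig.
#' @return data.frame with columns group, ts, tv, ratio.
#' @export
tsTvPanel <- function(panel, byContig = FALSE) {
  e <- panelEntries(panel)
  snv <- nchar(e$ref) == 1 & nchar(e$alt) == 1
  e <- e[snv, , drop = FALSE]
  grp <- if (byContig) e$contig else rep("all", nrow(e))
  ts <- .is_transition(e$ref, e$alt)
  agg <- stats::aggregate(cbind(ts = ts, tv = !ts),
                          by = list(group = grp), FUN = sum)
  agg$ratio <- ifelse(agg$tv > 0, agg$ts / agg$tv, NA_real_)
  agg
}

#' Per-sample transition/transversion ratios
#'
#' For each sample, counts the distinct SNV ALT alleles its genotype carries
#' as transitions or transversions. For X-chromosome call sets pass the
#' female sample subset (male haploid sites would otherwise skew the
#' comparison).
#'
#' @param cs a [VariantCallSet].
#' @param sampleIds samples to evaluate (default all).
#' @return data.frame with columns sample, ts, tv, ratio.
#' @export
tsTvPerSample <- function(cs, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- cs@samples
  altsplit <- strsplit(cs@sites$alt, ",", fixed = TRUE)
  snv_alt <- lapply(seq_along(altsplit), function(i) {
    ok <- nchar(cs@sites$ref[i]) == 1 & nchar(altsplit[[i]]) == 1
    which(ok)
  })
  out <- lapply(sampleIds, function(s) {
    si <- match(s, cs@samples)
    ts <- tv <- 0L
    for (i in seq_len(nrow(cs@sites))) {
      carried <- unique(c(cs@A1[si, i], cs@A2[si, i]))
      carried <- carried[!is.na(carried) & carried > 0]
      carried <- intersect(carried, snv_alt[[i]])
      if (!length(carried)) next
      tsk <- .is_transition(cs@sites$ref[i], altsplit[[i]][carried])
      ts <- ts + sum(tsk)
      tv <- tv + sum(!tsk)
    }
    data.frame(sample = s, ts = ts, tv = tv,
               ratio = if (tv > 0) ts / tv else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- accessibility ---------------------------------------------------------

#' Mean depth tracks under two MAPQ policies
#'
#' Averages per-base depth over samples for the all-reads and MAPQ >= 20
#' policies and returns their difference, an indicator of likely
#' multi-mapping (repeat) regions where low-MAPQ reads pile up.
#'
#' @param tracks list (one element per sample) of two-column matrices
#'   `cbind(all, mq20)` over the same coordinate span.
#' @return list with numeric vectors `all`, `mq20`, `diff`.
#' @export
meanDepthTrack <- function(tracks) {
  n <- unique(vapply(tracks, nrow, integer(1)))
  if (length(n) != 1)
    stop("alignment error: depth tracks cover different spans")
  allm <- rowMeans(vapply(tracks, function(t) t[, 1], numeric(n)))
  mq20 <- rowMeans(vapply(tracks, function(t) t[, 2], numeric(n)))
  list(all = allm, mq20 = mq20, diff = allm - mq20)
}

#' Write a per-base track as BedGraph
#'
#' Run-length-compresses equal adjacent values. BedGraph is 0-based
#' half-open; the conversion happens here at the boundary.
#'
#' @param values per-base values starting at `start` (1-based).
#' @param contig contig name.
#' @param path output path.
#' @param start 1-based position of the first value.
#' @export
writeBedGraph <- function(values, contig, path, start = 1) {
  r <- rle(values)
  e <- cumsum(r$lengths)
  s <- c(0, head(e, -1))
  writeLines(sprintf("%s\t%d\t%d\t%g", contig,
                     as.integer(start - 1 + s), as.integer(start - 1 + e),
                     r$values), path)
}
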