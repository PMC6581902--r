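# Population-structure workflow: Hardy-Weinberg exact test, variant
# filtering, dataset merging on common variants, LD pruning, PCA, and the
# outlier-cluster IBD check.

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on one variant's genotype counts: conditional on
#' the observed allele counts, the heterozygote count follows a
#' hypergeometric-form distribution over the values of matching parity; the
#' p-value is the total probability of heterozygote counts no more probable
#' than the observed one. Monomorphic input gives p = 1. The p-value is
#' invariant under swapping the homozygote counts.
#'
#' @param nAA,nAB,nBB genotype counts (hom-ref, het, hom-alt); vectors are
#'   recycled elementwise.
#' @return p-value(s) in (0, 1].
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  n <- max(length(nAA), length(nAB), length(nBB))
  nAA <- rep_len(nAA, n); nAB <- rep_len(nAB, n); nBB <- rep_len(nBB, n)
  vapply(seq_len(n), function(i) .hwe_one(nAA[i], nAB[i], nBB[i]),
         numeric(1))
}

.hwe_one <- function(a, b, c) {
  if (min(a, b, c) < 0 || a + b + c < 1) stop("counts must be >= 0, total >= 1")
  nA <- 2 * a + b
  nB <- 2 * c + b
  if (nA == 0 || nB == 0) return(1)
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  aa <- (nA - hs) / 2
  cc <- (nB - hs) / 2
  lw <- hs * log(2) - lgamma(aa + 1) - lgamma(hs + 1) - lgamma(cc + 1)
  w <- exp(lw - max(lw))
  pr <- w / sum(w)
  pobs <- pr[match(b, hs)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

#' Filter variants on MAF, Hardy-Weinberg p and missingness
#'
#' A variant survives iff its minor allele frequency (computed on
#' non-missing dosages) is at least `mafMin`, its Hardy-Weinberg exact-test
#' p-value is at least `hwePMin`, and its missing fraction is at most
#' `missingMax`. The removal log records the first failing criterion (MAF,
#' then HWE, then missingness) per removed variant. The operation is
#' idempotent.
#'
#' @param gm a [GenotypeMatrix] of diploid dosages.
#' @param mafMin,hwePMin,missingMax thresholds.
#' @return list: `gm` (filtered matrix), `log` (data.frame contig, pos, ref,
#'   alt, reason).
#' @export
filterVariants <- function(gm, mafMin = 0.01, hwePMin = 1e-5,
                           missingMax = 1) {
  d <- dosages(gm)
  if (ncol(d) == 0) stop("matrix is empty")
  nm <- colSums(!is.na(d))
  p <- ifelse(nm > 0, colSums(d, na.rm = TRUE) / (2 * nm), NA_real_)
  maf <- pmin(p, 1 - p)
  miss <- 1 - nm / nrow(d)
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  hwe <- rep(1, ncol(d))
  test <- which(nm > 0)
  hwe[test] <- hweExactTest(n0[test], n1[test], n2[test])
  failMaf <- is.na(maf) | maf < mafMin
  failHwe <- hwe < hwePMin
  failMiss <- miss > missingMax
  keep <- !(failMaf | failHwe | failMiss)
  reason <- ifelse(failMaf, "MAF", ifelse(failHwe, "HWE", "MISSING"))
  v <- gmVariants(gm)
  log <- data.frame(v[!keep, , drop = FALSE], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  out <- GenotypeMatrix(d[, keep, drop = FALSE], v[keep, , drop = FALSE],
                        samples = gmSamples(gm))
  list(gm = out, log = log)
}

#' Merge two genotype matrices on common variants
#'
#' The merged variant set is the intersection on (contig, pos, ref, alt)
#' after attempting ref/alt-swap harmonization (a swapped match contributes
#' dosages complemented as `2 - d`); the sample set is the union (column
#' order: `a`'s samples then `b`'s). Duplicate sample ids across inputs are
#' an error, as is an empty intersection.
#'
#' @param a,b [GenotypeMatrix]s with disjoint sample sets.
#' @return the combined [GenotypeMatrix] (variants in `a`'s orientation).
#' @export
mergeOnCommon <- function(a, b) {
  if (length(intersect(gmSamples(a), gmSamples(b))))
    stop("identity error: duplicate sample id across inputs")
  va <- gmVariants(a)
  vb <- gmVariants(b)
  key <- function(v) paste(v$contig, v$pos, v$ref, v$alt, sep = ":")
  swkey <- function(v) paste(v$contig, v$pos, v$alt, v$ref, sep = ":")
  direct <- match(key(va), key(vb))
  swp <- match(key(va), swkey(vb))
  use_sw <- is.na(direct) & !is.na(swp)
  bidx <- ifelse(use_sw, swp, direct)
  sel <- which(!is.na(bidx))
  if (!length(sel)) stop("empty-variant error: no common variants")
  da <- dosages(a)[, sel, drop = FALSE]
  db <- dosages(b)[, bidx[sel], drop = FALSE]
  flip <- use_sw[sel]
  db[, flip] <- 2 - db[, flip]
  GenotypeMatrix(rbind(da, db), va[sel, , drop = FALSE],
                 samples = c(gmSamples(a), gmSamples(b)))
}

# squared Pearson correlation between one dosage column and a block
.r2_vs <- function(x, block) {
  if (anyNA(x) || anyNA(block)) {
    suppressWarnings(as.vector(stats::cor(x, block,
                                          use = "pairwise.complete.obs"))^2)
  } else {
    xc <- x - mean(x)
    bc <- sweep(block, 2, colMeans(block))
    num <- as.vector(crossprod(xc, bc))
    den <- sqrt(sum(xc^2) * colSums(bc^2))
    ifelse(den > 0, (num / den)^2, NA_real_)
  }
}

#' LD pruning by pairwise dosage correlation
#'
#' Slides a window of `windowVariants` variants advancing by `stepVariants`;
#' whenever a within-window pair of kept variants has squared Pearson
#' correlation of dosages above `r2Threshold`, the member with the lower
#' minor allele frequency is removed (ties: the later position). The final
#' kept set is re-audited over every window position on every run — no kept
#' within-window pair exceeds the threshold. Defaults mirror the
#' `--indep-pairwise 200 4 0.1` parameterization (window and step in variant
#' counts).
#'
#' @param gm a [GenotypeMatrix].
#' @param windowVariants,stepVariants window/step sizes in variants.
#' @param r2Threshold maximum squared correlation allowed.
#' @return list: `keptIdx` (variant indices), `gm` (pruned matrix).
#' @export
ldPrune <- function(gm, windowVariants = 200, stepVariants = 4,
                    r2Threshold = 0.1) {
  if (stepVariants < 1 || windowVariants <= stepVariants)
    stop("window must exceed step, step >= 1")
  if (r2Threshold <= 0 || r2Threshold > 1)
    stop("r2 threshold must lie in (0, 1]")
  d <- dosages(gm)
  m <- ncol(d)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  kept <- rep(TRUE, m)
  starts <- unique(c(seq(1, max(1, m - 1), by = stepVariants)))
  checked_to <- 0L
  for (w in starts) {
    hi <- min(w + windowVariants - 1L, m)
    newcomers <- seq(max(w, checked_to + 1L), hi)
    newcomers <- newcomers[kept[newcomers]]
    for (v in newcomers) {
      others <- which(kept[w:hi]) + w - 1L
      others <- setdiff(others[others < v], v)
      if (!length(others)) next
      r2 <- .r2_vs(d[, v], d[, others, drop = FALSE])
      bad <- others[!is.na(r2) & r2 > r2Threshold]
      for (u in bad) {
        if (!kept[u] || !kept[v]) next
        drop <- if (maf[u] < maf[v]) u else if (maf[v] < maf[u]) v else
          max(u, v)
        kept[drop] <- FALSE
      }
      if (!kept[v]) next
    }
    checked_to <- hi
    if (hi == m) break
  }
  # post-condition audit over every window position
  for (w in starts) {
    hi <- min(w + windowVariants - 1L, m)
    idx <- which(kept[w:hi]) + w - 1L
    if (length(idx) < 2) next
    cm <- if (anyNA(d[, idx]))
      suppressWarnings(stats::cor(d[, idx], use = "pairwise.complete.obs")) else
        stats::cor(d[, idx])
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    stopifnot(max(cm^2) <= r2Threshold + 1e-12)
    if (hi == m) break
  }
  keptIdx <- which(kept)
  list(keptIdx = keptIdx,
       gm = GenotypeMatrix(d[, keptIdx, drop = FALSE],
                           gmVariants(gm)[keptIdx, , drop = FALSE],
                           samples = gmSamples(gm)))
}

#' PCA of a genotype matrix
#'
#' Missing dosages are mean-imputed; each variant is standardized by
#' subtracting `2p` and dividing by `sqrt(2p(1-p))` (`p` the estimated
#' alternative allele frequency); components come from the
#' eigen-decomposition of the sample x sample covariance of the standardized
#' matrix. Sample coordinates are eigenvectors scaled by the square root of
#' their eigenvalue, with the deterministic sign convention that each
#' component's largest-magnitude coordinate is positive.
#'
#' @param gm a [GenotypeMatrix] (>= 2 samples, >= 2 variants, no
#'   zero-variance variant — filter first).
#' @param k number of components (default 10, capped at sample count).
#' @return list: `scores` (samples x k), `eigenvalues` (descending, all).
#' @export
pcaGenotypes <- function(gm, k = 10) {
  d <- dosages(gm)
  if (nrow(d) < 2 || ncol(d) < 2) stop("need >= 2 samples and >= 2 variants")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(d) / 2
  sdv <- sqrt(2 * p * (1 - p))
  v <- colSums(sweep(d, 2, colMeans(d))^2)
  if (any(sdv == 0 | v == 0))
    stop("internal error: zero-variance variant reached PCA; filter first")
  x <- sweep(sweep(d, 2, 2 * p), 2, sdv, "/")
  C <- tcrossprod(x) / ncol(x)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  k <- min(k, nrow(d))
  sc <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sc[, j]))
    if (sc[i, j] < 0) sc[, j] <- -sc[, j]
  }
  rownames(sc) <- gmSamples(gm)
  colnames(sc) <- paste0("PC", seq_len(k))
  list(scores = sc, eigenvalues = vals)
}

#' Maximum pairwise IBD within a sample subset
#'
#' Runs the method-of-moments IBD estimator over all pairs of the subset
#' (allele frequencies from the full matrix) and returns the maximum PIHAT
#' and the pair attaining it. Used to check whether a PCA outlier cluster is
#' driven by relatedness.
#'
#' @param gm a [GenotypeMatrix].
#' @param subsetIds sample ids (>= 2) forming the cluster.
#' @param minMarkers see [estimateIbd()].
#' @return list: `maxPihat`, `pair`, `table` (all pairwise estimates).
#' @export
clusterIbdCheck <- function(gm, subsetIds, minMarkers = 500) {
  if (length(subsetIds) < 2) stop("subset must contain >= 2 samples")
  cmb <- utils::combn(subsetIds, 2)
  tab <- estimateIbdMatrix(gm, pairs = cbind(cmb[1, ], cmb[2, ]),
                           minMarkers = minMarkers)
  i <- which.max(tab$pihat)
  list(maxPihat = tab$pihat[i], pair = c(tab$id1[i], tab$id2[i]),
       table = tab)
}
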