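# Sample-level QC: X-inbreeding sex inference with Y-depth consistency,
# method-of-moments IBD/PIHAT relatedness, and greedy relative pruning.

#' Infer sample sex from X heterozygosity and Y depth
#'
#' Computes the method-of-moments inbreeding coefficient on non-PAR X
#' markers, `F = (observed hom - expected hom) / (markers - expected hom)`
#' with expected hom `sum(1 - 2p(1-p))`, and calls male when `F` is at or
#' above the upper threshold and female at or below the lower one. The
#' Y/autosome mean-depth ratio must agree with the call (>= `yMale` for
#' males, <= `yFemale` for females); any disagreement — including the
#' irregular-karyotype signature of a homozygous X with no Y depth — yields
#' an `ambiguous` call, which excludes the sample from panel construction.
#'
#' @param xDosage dosages (0/1/2, NA missing) of one sample at non-PAR X
#'   markers, het coded 1. Haploid male calls must be hom-coded (0/2).
#' @param xFreqs alternative allele frequencies of the same markers.
#' @param yDepthRatio mean Y depth / mean autosome depth.
#' @param fUpper,fLower F thresholds for male/female calls (defaults
#'   0.8/0.2).
#' @param yMale,yFemale Y-ratio cut-offs (defaults 0.3/0.1).
#' @param minMarkers minimum informative markers (default 50).
#' @return data.frame row: F, yDepthRatio, call.
#' @export
inferSex <- function(xDosage, xFreqs, yDepthRatio, fUpper = 0.8,
                     fLower = 0.2, yMale = 0.3, yFemale = 0.1,
                     minMarkers = 50) {
  keep <- !is.na(xDosage) & xFreqs > 0 & xFreqs < 1
  if (sum(keep) < minMarkers)
    stop(sprintf("insufficient-data error: %d informative X markers (< %d)",
                 sum(keep), minMarkers))
  d <- xDosage[keep]
  p <- xFreqs[keep]
  m <- length(d)
  obsHom <- sum(d != 1)
  expHom <- sum(1 - 2 * p * (1 - p))
  f <- (obsHom - expHom) / (m - expHom)
  call <- if (f >= fUpper) "male" else if (f <= fLower) "female" else
    "ambiguous"
  if (call == "male" && yDepthRatio < yMale) call <- "ambiguous"
  if (call == "female" && yDepthRatio > yFemale) call <- "ambiguous"
  data.frame(F = f, yDepthRatio = yDepthRatio, call = call,
             stringsAsFactors = FALSE)
}

#' @rdname inferSex
#' @param xMatrix samples x markers dosage matrix (rownames = sample ids).
#' @param yDepthRatios named per-sample ratios.
#' @param ... passed to `inferSex`.
#' @export
inferSexAll <- function(xMatrix, xFreqs, yDepthRatios, ...) {
  out <- lapply(seq_len(nrow(xMatrix)), function(i)
    inferSex(xMatrix[i, ], xFreqs, yDepthRatios[i], ...))
  res <- do.call(rbind, out)
  res <- cbind(data.frame(id = rownames(xMatrix),
                          stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

# per-marker P(IBS = i | IBD = z) expectations with the finite-sample allele
# count corrections of the PLINK method-of-moments estimator
.ibd_expectations <- function(p, nAlleles) {
  q <- 1 - p
  Na <- nAlleles
  x <- p * Na
  y <- q * Na
  c3 <- Na / (Na - 1) * Na / (Na - 2) * Na / (Na - 3)
  c2 <- Na / (Na - 1) * Na / (Na - 2)
  list(
    e00 = 2 * p^2 * q^2 * ((x - 1) / x) * ((y - 1) / y) * c3,
    e10 = 4 * p^3 * q * ((x - 1) / x) * ((x - 2) / x) * c3 +
      4 * p * q^3 * ((y - 1) / y) * ((y - 2) / y) * c3,
    e20 = p^4 * ((x - 1) / x) * ((x - 2) / x) * ((x - 3) / x) * c3 +
      q^4 * ((y - 1) / y) * ((y - 2) / y) * ((y - 3) / y) * c3 +
      4 * p^2 * q^2 * ((x - 1) / x) * ((y - 1) / y) * c3,
    e11 = 2 * p^2 * q * ((x - 1) / x) * c2 +
      2 * p * q^2 * ((y - 1) / y) * c2,
    e21 = p^3 * ((x - 1) / x) * ((x - 2) / x) * c2 +
      q^3 * ((y - 1) / y) * ((y - 2) / y) * c2 +
      p^2 * q * ((x - 1) / x) * c2 + p * q^2 * ((y - 1) / y) * c2)
}

#' Method-of-moments IBD estimate for one sample pair
#'
#' Counts identity-by-state (IBS) 0/1/2 over shared non-missing diploid
#' markers, computes the expected IBS distribution given IBD state from the
#' marker allele frequencies (with the finite-sample allele count bias
#' corrections of the standard method-of-moments estimator), solves for
#' (Z0, Z1, Z2) by the method of moments, clips the solution to [0, 1] and
#' renormalizes. `PIHAT = Z2 + Z1/2`. The estimator assumes approximately
#' independent markers — feed it LD-pruned autosomal dosages.
#'
#' @param d1,d2 dosage vectors (0/1/2, NA missing) for the two samples.
#' @param freqs alternative allele frequencies; markers with frequency 0 or 1
#'   are dropped.
#' @param nAlleles number of alleles the frequencies were estimated from
#'   (2 x sample count).
#' @param minMarkers minimum shared informative markers (default 500).
#' @return data.frame row: z0, z1, z2, pihat, nMarkers.
#' @export
estimateIbd <- function(d1, d2, freqs, nAlleles, minMarkers = 500) {
  keep <- !is.na(d1) & !is.na(d2) & freqs > 0 & freqs < 1
  if (!any(freqs > 0 & freqs < 1))
    stop("degenerate-frequency error: all markers monomorphic")
  m <- sum(keep)
  if (m < minMarkers)
    stop(sprintf("insufficient-data error: %d shared markers (< %d)", m,
                 minMarkers))
  ibs <- 2 - abs(d1[keep] - d2[keep])
  o <- c(mean(ibs == 0), mean(ibs == 1), mean(ibs == 2))
  ex <- .ibd_expectations(freqs[keep], nAlleles)
  e00 <- mean(ex$e00); e10 <- mean(ex$e10); e20 <- mean(ex$e20)
  e11 <- mean(ex$e11); e21 <- mean(ex$e21)
  z0 <- o[1] / e00
  z1 <- (o[2] - z0 * e10) / e11
  z2 <- (o[3] - z0 * e20 - z1 * e21)
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  data.frame(z0 = z[1], z1 = z[2], z2 = z[3], pihat = z[3] + z[2] / 2,
             nMarkers = m)
}

#' All pairwise IBD estimates over a genotype matrix
#'
#' @param gm a [GenotypeMatrix] of (LD-pruned) autosomal dosages; allele
#'   frequencies are estimated from the matrix itself.
#' @param pairs optional two-column matrix of sample ids to restrict to.
#' @param minMarkers see [estimateIbd()].
#' @return data.frame: id1, id2, z0, z1, z2, pihat, nMarkers.
#' @export
estimateIbdMatrix <- function(gm, pairs = NULL, minMarkers = 500) {
  d <- dosages(gm)
  ids <- gmSamples(gm)
  freqs <- colMeans(d, na.rm = TRUE) / 2
  nAll <- 2 * nrow(d)
  if (is.null(pairs)) {
    cmb <- utils::combn(ids, 2)
    pairs <- cbind(cmb[1, ], cmb[2, ])
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- match(pairs[k, 1], ids)
    j <- match(pairs[k, 2], ids)
    est <- estimateIbd(d[i, ], d[j, ], freqs, nAll, minMarkers = minMarkers)
    cbind(data.frame(id1 = ids[i], id2 = ids[j],
                     stringsAsFactors = FALSE), est)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Greedy relatedness pruning
#'
#' Repeatedly removes the sample participating in the most over-threshold
#' PIHAT pairs (ties broken by lower genotype call rate, then lexicographic
#' id) until no kept pair is at or above the threshold. The default
#' threshold, 0.1875, is the midpoint between the second-degree (0.25) and
#' third-degree (0.125) expectations, so relationships closer than third
#' degree are removed. The kept set is re-verified on every run.
#'
#' @param ibd data.frame with id1, id2, pihat (all candidate pairs).
#' @param threshold PIHAT exclusion threshold.
#' @param callRates optional named per-sample genotype call rates for tie
#'   breaking.
#' @return list: `kept` (ids), `excluded` (data.frame id, pihat,
#'   triggeringPair).
#' @export
pruneRelatives <- function(ibd, threshold = 0.1875, callRates = NULL) {
  ids <- sort(unique(c(ibd$id1, ibd$id2)))
  if (is.null(callRates))
    callRates <- stats::setNames(rep(1, length(ids)), ids)
  edges <- ibd[ibd$pihat >= threshold, , drop = FALSE]
  removed <- list()
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      cr <- callRates[cand]
      cand <- cand[cr == min(cr)]
    }
    drop_id <- sort(cand)[1]
    hit <- edges[edges$id1 == drop_id | edges$id2 == drop_id, , drop = FALSE]
    top <- hit[which.max(hit$pihat), ]
    removed[[length(removed) + 1]] <- data.frame(
      id = drop_id, pihat = top$pihat,
      triggeringPair = paste(top$id1, top$id2, sep = "-"),
      stringsAsFactors = FALSE)
    edges <- edges[edges$id1 != drop_id & edges$id2 != drop_id, ,
                   drop = FALSE]
  }
  excluded <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(0), pihat = numeric(0),
               triggeringPair = character(0), stringsAsFactors = FALSE)
  kept <- setdiff(ids, excluded$id)
  over <- ibd$id1 %in% kept & ibd$id2 %in% kept & ibd$pihat >= threshold
  stopifnot(!any(over))
  list(kept = kept, excluded = excluded)
}

#' Extract a dosage matrix from a call set
#'
#' Expands each (site, ALT) combination to a dosage column; haploid
#' genotypes contribute dosage 0/1.
#'
#' @param cs a [VariantCallSet].
#' @return a [GenotypeMatrix].
#' @export
genotypeMatrix <- function(cs) {
  nv <- nrow(cs@sites)
  altsplit <- strsplit(cs@sites$alt, ",", fixed = TRUE)
  cols <- list()
  vars <- list()
  for (i in seq_len(nv)) {
    for (k in seq_len(cs@sites$nalt[i])) {
      dcol <- (cs@A1[, i] == k) + ifelse(is.na(cs@A2[, i]) &
                                           cs@PLOIDY[, i] == 1L, 0L,
                                         cs@A2[, i] == k)
      cols[[length(cols) + 1]] <- dcol
      vars[[length(vars) + 1]] <- data.frame(
        contig = cs@sites$contig[i], pos = cs@sites$pos[i],
        ref = cs@sites$ref[i], alt = altsplit[[i]][k],
        stringsAsFactors = FALSE)
    }
  }
  GenotypeMatrix(do.call(cbind, cols), do.call(rbind, vars),
                 samples = cs@samples)
}
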