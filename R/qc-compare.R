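# Evaluation machinery: WGS-vs-array genotype concordance and cross-panel
# allele frequency comparison.

.state_levels <- c("NotObserved", "NoCall", "HomRef", "Het", "HomAlt")

# align array markers with per-ALT WGS sites on (contig, pos), attempting a
# ref/alt swap before declaring a marker unharmonizable
.harmonize_markers <- function(wgs, arr) {
  key <- function(ct, p) paste(ct, p, sep = ":")
  m <- merge(arr, wgs, by = c("contig", "pos"), all = TRUE,
             suffixes = c(".arr", ".wgs"))
  direct <- !is.na(m$ref.arr) & !is.na(m$ref.wgs) &
    m$ref.arr == m$ref.wgs & m$alt.arr == m$alt.wgs
  swapped <- !is.na(m$ref.arr) & !is.na(m$ref.wgs) &
    m$ref.arr == m$alt.wgs & m$alt.arr == m$ref.wgs
  mismatch <- !is.na(m$ref.arr) & !is.na(m$ref.wgs) & !direct & !swapped
  list(map = m, direct = direct, swapped = swapped, mismatch = mismatch)
}

#' WGS vs array genotype concordance matrix
#'
#' Cross-tabulates, over a marker universe (the union of array markers and
#' the call set's sites), every marker x sample observation into the 5x5
#' state grid NotObserved / NoCall / HomRef / Het / HomAlt. A WGS state is
#' NotObserved when the call set has no site at the marker, NoCall when the
#' site exists but the sample genotype is missing. Markers whose alleles
#' cannot be harmonized (after a ref/alt swap attempt) are excluded and
#' logged. Haploid WGS genotypes count as homozygous, mirroring array
#' reporting.
#'
#' @param cs a [VariantCallSet] (the WGS side).
#' @param arrayTable array genotype table ([emitArrayGenotypes()] layout).
#' @param samples samples to tabulate (default: those present on both
#'   sides).
#' @param perSample also return one matrix per sample.
#' @return a [ConcordanceMatrix]; excluded markers are attached as
#'   attribute `"excluded"`.
#' @export
concordanceMatrix <- function(cs, arrayTable, samples = NULL,
                              perSample = FALSE) {
  at <- data.table::as.data.table(arrayTable)
  meta <- c("contig", "pos", "ref", "alt")
  arr_samples <- setdiff(names(at), meta)
  if (is.null(samples)) samples <- intersect(cs@samples, arr_samples)
  if (!length(samples)) stop("no samples shared between call set and array")

  # per-ALT decomposition of WGS sites (biallelic keys)
  altsplit <- strsplit(cs@sites$alt, ",", fixed = TRUE)
  wgs <- do.call(rbind, lapply(seq_len(nrow(cs@sites)), function(i)
    data.frame(contig = cs@sites$contig[i], pos = cs@sites$pos[i],
               ref = cs@sites$ref[i], alt = altsplit[[i]],
               siteIdx = i, altIdx = seq_along(altsplit[[i]]),
               stringsAsFactors = FALSE)))
  if (is.null(wgs))
    wgs <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      siteIdx = integer(0), altIdx = integer(0))
  arr <- as.data.frame(at[, meta, with = FALSE])
  arr$arrRow <- seq_len(nrow(arr))
  h <- .harmonize_markers(wgs, arr)
  m <- h$map
  excluded <- m[h$mismatch, c("contig", "pos"), drop = FALSE]
  use <- !h$mismatch
  m <- m[use, , drop = FALSE]
  direct <- h$direct[use]
  swapped <- h$swapped[use]

  si <- m$siteIdx
  ai <- m$altIdx
  arow <- m$arrRow
  nmk <- nrow(m)
  tab_template <- matrix(0, 5, 5, dimnames = list(WGS = .state_levels,
                                                  Array = .state_levels))
  per <- list()
  total <- tab_template
  gmat <- as.matrix(at[, samples, with = FALSE])
  for (s in samples) {
    srow <- match(s, cs@samples)
    # WGS state
    wgs_state <- rep("NotObserved", nmk)
    has_site <- !is.na(si)
    idx <- which(has_site)
    a1 <- cs@A1[srow, si[idx]]
    a2 <- cs@A2[srow, si[idx]]
    pld <- cs@PLOIDY[srow, si[idx]]
    dose <- ifelse(pld == 1L, (a1 == ai[idx]) * 2L,
                   (a1 == ai[idx]) + (a2 == ai[idx]))
    st <- ifelse(is.na(a1), "NoCall",
                 c("HomRef", "Het", "HomAlt")[dose + 1L])
    wgs_state[idx] <- st
    # array state
    arr_state <- rep("NotObserved", nmk)
    aidx <- which(!is.na(arow))
    g <- gmat[arow[aidx], match(s, samples)]
    ast <- ifelse(g == "NoCall", "NoCall",
                  ifelse(g == "0/0", "HomRef",
                         ifelse(g == "0/1", "Het", "HomAlt")))
    sw <- swapped[aidx]
    ast[sw & ast == "HomRef"] <- "tmp"
    ast[sw & ast == "HomAlt"] <- "HomRef"
    ast[ast == "tmp"] <- "HomAlt"
    arr_state[aidx] <- ast
    tab <- table(factor(wgs_state, levels = .state_levels),
                 factor(arr_state, levels = .state_levels))
    tab <- unclass(tab)
    dimnames(tab) <- dimnames(tab_template)
    total <- total + tab
    if (perSample) per[[s]] <- tab
  }
  total[1, 1] <- NA
  if (perSample) for (s in names(per)) per[[s]][1, 1] <- NA
  out <- new("ConcordanceMatrix", counts = total,
             perSample = if (perSample) per else NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Genotype concordance ratio
#'
#' Fraction of jointly-called observations (both sides report a genotype;
#' NoCall and NotObserved rows/columns excluded) on the HomRef/Het/HomAlt
#' diagonal. Symmetric under swapping the WGS and array roles. NA when
#' nothing is jointly called.
#'
#' @param cm a [ConcordanceMatrix] or a plain 5x5 matrix in the same layout.
#' @return concordance fraction in [0, 1], or NA.
#' @export
concordanceRatio <- function(cm) {
  counts <- if (is(cm, "ConcordanceMatrix")) cm@counts else cm
  g <- counts[3:5, 3:5]
  tot <- sum(g)
  if (tot == 0) return(NA_real_)
  sum(diag(g)) / tot
}

#' Compare two allele frequency panels
#'
#' Matches panel entries per-ALT on (contig, pos, ref, alt) — attempting a
#' ref/alt swap with allele frequency complementation before declaring a
#' variant panel-specific — computes the Pearson correlation of shared
#' alternative allele frequencies, and reports outliers with
#' `|af_a - af_b| >= threshold`, each annotated with any overlapping region
#' mask (e.g. a low-complexity BED) or `"Unknown"`.
#'
#' @param panelA,panelB [FrequencyPanel]s on the same coordinate system.
#' @param threshold outlier |AF difference| threshold in (0, 1] (default
#'   0.3).
#' @param masks optional named list of region data.frames (contig, start,
#'   end, 1-based inclusive) used to annotate outliers.
#' @return list: `shared` (data.frame with afA, afB, swapped), `aOnly`,
#'   `bOnly`, `r` (NA when < 2 shared pairs), `outliers` (with `annotation`
#'   column).
#' @export
comparePanels <- function(panelA, panelB, threshold = 0.3, masks = NULL) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  a <- panelEntries(panelA)
  b <- panelEntries(panelB)
  key <- function(e) paste(e$contig, e$pos, e$ref, e$alt, sep = ":")
  swkey <- function(e) paste(e$contig, e$pos, e$alt, e$ref, sep = ":")
  ka <- key(a)
  kb <- key(b)
  direct <- match(ka, kb)
  swp <- match(ka, swkey(b))
  use_sw <- is.na(direct) & !is.na(swp)
  bidx <- ifelse(use_sw, swp, direct)
  shared_i <- which(!is.na(bidx))
  shared <- data.frame(a[shared_i, c("contig", "pos", "ref", "alt")],
                       afA = a$af[shared_i],
                       afB = ifelse(use_sw[shared_i],
                                    1 - b$af[bidx[shared_i]],
                                    b$af[bidx[shared_i]]),
                       swapped = use_sw[shared_i],
                       stringsAsFactors = FALSE)
  aOnly <- a[is.na(bidx), c("contig", "pos", "ref", "alt", "af"),
             drop = FALSE]
  bseen <- stats::na.omit(bidx)
  bOnly <- b[setdiff(seq_len(nrow(b)), bseen),
             c("contig", "pos", "ref", "alt", "af"), drop = FALSE]
  r <- if (nrow(shared) >= 2) stats::cor(shared$afA, shared$afB) else
    NA_real_
  out <- shared[abs(shared$afA - shared$afB) >= threshold, , drop = FALSE]
  if (nrow(out)) {
    out$annotation <- vapply(seq_len(nrow(out)), function(i) {
      hits <- character(0)
      for (nm in names(masks)) {
        mk <- masks[[nm]]
        if (any(mk$contig == out$contig[i] & mk$start <= out$pos[i] &
                  mk$end >= out$pos[i]))
          hits <- c(hits, nm)
      }
      if (length(hits)) paste(hits, collapse = ",") else "Unknown"
    }, character(1))
  } else {
    out$annotation <- character(0)
  }
  rownames(out) <- NULL
  list(shared = shared, aOnly = aOnly, bOnly = bOnly, r = r, outliers = out)
}
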