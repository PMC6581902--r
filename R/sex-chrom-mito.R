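# X-chromosome region classification, dual PAR-convention panels, the XTR
# heterozygosity scan, and circular-mitochondria calling on two shifted
# linearizations.

#' Classify an X-chromosome position
#'
#' Returns the named sub-region (`PAR1`, `XTR`, `PAR2`) containing each
#' position, or `NONPAR`. Under the `TWO_PAR` convention XTR positions are
#' reported as `NONPAR` (the XTR is then treated like the rest of the
#' X-specific sequence).
#'
#' @param pos position(s) on the X contig.
#' @param xmap an [XRegionMap].
#' @param mode convention override; defaults to the map's mode.
#' @param contigLength optional X length for range checking.
#' @return character vector in {PAR1, XTR, PAR2, NONPAR}.
#' @export
classifyXRegion <- function(pos, xmap, mode = NULL, contigLength = NULL) {
  if (is.null(mode)) mode <- xmap@mode
  if (!is.null(contigLength) && (any(pos < 1) || any(pos > contigLength)))
    stop("range error: position outside X contig")
  out <- rep("NONPAR", length(pos))
  out[regionContains(xmap@par1, pos)] <- "PAR1"
  out[regionContains(xmap@par2, pos)] <- "PAR2"
  in_xtr <- regionContains(xmap@xtr, pos)
  out[in_xtr] <- if (mode == "THREE_PAR") "XTR" else "NONPAR"
  out
}

#' Resolve expected ploidies for a set of sites
#'
#' @param pmap a [PloidyMap].
#' @param category contig category (autosome, chrX, mito).
#' @param pos positions on the contig.
#' @return integer matrix, samples (in `pmap` order) x positions.
#' @export
resolvePloidy <- function(pmap, category, pos) {
  ns <- length(pmap@sexes)
  nv <- length(pos)
  if (category == "autosome")
    return(matrix(2L, ns, nv))
  if (category == "mito")
    return(matrix(1L, ns, nv))
  if (category == "chrY")
    stop("no variant-level ploidy is defined on the Y chromosome")
  if (is.null(pmap@xmap)) stop("PloidyMap needs an XRegionMap for chrX sites")
  reg <- classifyXRegion(pos, pmap@xmap, mode = pmap@mode)
  diploid_region <- reg != "NONPAR"
  male <- pmap@sexes == "male"
  m <- matrix(2L, ns, nv)
  m[male, !diploid_region] <- 1L
  m
}

#' Adjust per-sample X records to a PAR convention
#'
#' Desk-scale equivalent of re-calling the X under a different ploidy
#' configuration: for male samples, a diploid record at a position the
#' convention treats as haploid is collapsed to one allele (the one with the
#' larger allele depth; ties to the lower allele index), and a haploid record
#' at a position the convention treats as diploid is expanded to a homozygous
#' diploid genotype. Female records are untouched.
#'
#' @param records combined record table for the X contig.
#' @param sexes named character vector ("male"/"female") per sample.
#' @param xmap an [XRegionMap].
#' @param mode `"TWO_PAR"` or `"THREE_PAR"`.
#' @return adjusted record table.
#' @export
prepareXRecords <- function(records, sexes, xmap, mode) {
  rec <- data.table::as.data.table(records)
  male <- rec$sample %in% names(sexes)[sexes == "male"]
  reg <- classifyXRegion(rec$pos, xmap, mode = mode)
  target <- ifelse(!male | reg != "NONPAR", 2L, 1L)
  called <- !is.na(rec$ploidy)
  collapse <- called & rec$ploidy == 2L & target == 1L
  expand <- called & rec$ploidy == 1L & target == 2L
  if (any(collapse)) {
    idx <- which(collapse)
    keep <- rec$a1[idx]
    hets <- idx[!is.na(rec$a1[idx]) & !is.na(rec$a2[idx]) &
                  rec$a1[idx] != rec$a2[idx]]
    if (length(hets)) {
      pick_allele <- function(i) {
        ad <- suppressWarnings(as.numeric(strsplit(rec$ad[i], ",")[[1]]))
        a <- rec$a1[i]; b <- rec$a2[i]
        ada <- if (length(ad) > a) ad[a + 1] else NA_real_
        adb <- if (length(ad) > b) ad[b + 1] else NA_real_
        if (!is.na(ada) && !is.na(adb) && adb > ada) b
        else if (!is.na(ada) && !is.na(adb) && ada > adb) a
        else min(a, b)
      }
      keep[match(hets, idx)] <- vapply(hets, pick_allele, integer(1))
    }
    rec$a1[idx] <- keep
    rec$a2[idx] <- NA_integer_
    rec$ploidy[idx] <- 1L
    rec$pl[idx] <- NA_character_
  }
  if (any(expand)) {
    idx <- which(expand)
    rec$a2[idx] <- rec$a1[idx]
    rec$ploidy[idx] <- 2L
    rec$pl[idx] <- NA_character_
  }
  rec
}

#' Build X-chromosome panels under both PAR conventions
#'
#' Runs the joint genotyping step twice over the same per-sample X records,
#' once with only PAR1/PAR2 diploid in males (`TWO_PAR`) and once with the
#' XTR also treated as pseudoautosomal (`THREE_PAR`). Records are first
#' reconciled with each convention via [prepareXRecords()]. Outside the XTR
#' the two panels are identical by construction.
#'
#' @param records combined X record table (all samples).
#' @param sexes named character vector ("male"/"female"); ambiguous-sex
#'   samples must be excluded upstream.
#' @param xmap an [XRegionMap].
#' @param contigLength X contig length (defaults to the largest record
#'   position).
#' @return list with elements `two_par` and `three_par`, each a list of
#'   `callset` ([VariantCallSet]) and `panel` ([FrequencyPanel]).
#' @export
buildXPanels <- function(records, sexes, xmap, contigLength = NULL) {
  rec <- data.table::as.data.table(records)
  if (is.null(contigLength)) contigLength <- max(rec$pos)
  xcontig <- unique(rec$contig)
  if (length(xcontig) != 1) stop("X records must live on a single contig")
  region <- Region(xcontig, 1, contigLength)
  one <- function(mode) {
    prep <- prepareXRecords(rec, sexes, xmap, mode)
    pmap <- PloidyMap(sexes, xmap, mode)
    cs <- jointGenotypeRegion(prep, region, pmap, category = "chrX")
    list(callset = cs, panel = computeFrequencies(cs))
  }
  list(two_par = one("TWO_PAR"), three_par = one("THREE_PAR"))
}

#' Windowed male X heterozygosity from array genotypes
#'
#' Scans position-sorted X array markers in non-overlapping windows of
#' `windowMarkers` markers and reports, per window, the fraction of called
#' male genotypes that are heterozygous. In truly X-specific (haploid male)
#' sequence this rate is 0 up to genotyping error; pseudoautosomal segments
#' show elevated rates, which is the signal used to decide whether the XTR
#' deserves pseudoautosomal treatment.
#'
#' @param arrayTable marker table (contig, pos, ref, alt, one genotype column
#'   per sample with values 0/0, 0/1, 1/1 or NoCall).
#' @param sexes named character vector per sample.
#' @param xmap an [XRegionMap] (used to annotate windows; named regions are
#'   always reported under their own names).
#' @param windowMarkers markers per window.
#' @param xContig contig name of the X markers (default the map's contig).
#' @return data.frame: window index, start/end positions, marker count,
#'   called genotypes, het count, het rate (NA when nothing called), and the
#'   named region(s) the window overlaps ("NONPAR" if none).
#' @export
xtrHeterozygosityScan <- function(arrayTable, sexes, xmap, windowMarkers = 20,
                                  xContig = NULL) {
  if (is.null(xContig)) xContig <- xmap@par1@contig
  at <- data.table::as.data.table(arrayTable)
  at <- at[at$contig == xContig]
  if (nrow(at) == 0) stop("no X markers in the array table")
  data.table::setorder(at, pos)
  males <- names(sexes)[sexes == "male"]
  males <- intersect(males, names(at))
  if (length(males) == 0) stop("at least one male sample is required")
  g <- as.matrix(at[, males, with = FALSE])
  called <- g %in% c("0/0", "0/1", "1/1")
  dim(called) <- dim(g)
  het <- g == "0/1"
  win <- (seq_len(nrow(at)) - 1L) %/% windowMarkers + 1L
  out <- lapply(split(seq_len(nrow(at)), win), function(idx) {
    calls <- sum(called[idx, , drop = FALSE])
    hets <- sum(het[idx, , drop = FALSE] & called[idx, , drop = FALSE])
    s <- min(at$pos[idx]); e <- max(at$pos[idx])
    regs <- unique(classifyXRegion(c(s, e, at$pos[idx]), xmap,
                                   mode = "THREE_PAR"))
    regs <- setdiff(regs, "NONPAR")
    data.frame(start = s, end = e, nMarkers = length(idx), calls = calls,
               hets = hets, rate = if (calls > 0) hets / calls else NA_real_,
               region = if (length(regs)) paste(regs, collapse = ",")
                        else "NONPAR")
  })
  res <- do.call(rbind, out)
  res <- cbind(window = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Map a shifted-linearization position to primary coordinates
#'
#' The circular mitochondrial genome is linearized twice: once at the
#' reference breakpoint (primary) and once with the breakpoint shifted by
#' `shift` bases, so that calls near either breakpoint can be taken from the
#' linearization in which they are interior. Position `pos` on the shifted
#' linearization corresponds to `((pos + shift - 1) mod L) + 1` on the
#' primary one; the map is a bijection on `[1, L]`.
#'
#' @param pos position(s) on the shifted linearization.
#' @param L circular genome length (rCRS: 16,569).
#' @param shift breakpoint shift in bases (default 10,000).
#' @return position(s) on the primary linearization.
#' @export
mtRemap <- function(pos, L, shift = 10000) {
  if (shift <= 0 || shift >= L) stop("shift must satisfy 0 < shift < L")
  if (any(pos < 1) || any(pos > L)) stop("range error: position outside [1, L]")
  ((pos + shift - 1) %% L) + 1
}

#' @rdname mtRemap
#' @export
mtUnmap <- function(pos, L, shift = 10000) {
  if (shift <= 0 || shift >= L) stop("shift must satisfy 0 < shift < L")
  if (any(pos < 1) || any(pos > L)) stop("range error: position outside [1, L]")
  ((pos - shift - 1) %% L) + 1
}

#' Call the mitochondrial panel from two linearizations
#'
#' Joint-genotypes the haploid mitochondrial records called against each
#' linearization, remaps the shifted call set to primary coordinates, and
#' merges edge-aware: sites at least `edgeMargin` bases from both primary
#' breakpoint ends come from the primary call set; sites within `edgeMargin`
#' of a primary end come from the shifted call set (which is breakpoint-free
#' there). Any residual duplicate positions collapse to one record, shifted
#' winning inside the swap zone and primary elsewhere.
#'
#' @param primaryRecords,shiftedRecords record tables on the two
#'   linearizations (same contig name, coordinates in each linearization's
#'   own frame); all genotypes must be haploid.
#' @param L mitochondrial genome length.
#' @param shift breakpoint shift used for the second linearization.
#' @param edgeMargin swap-zone width at each end of the primary
#'   linearization, in bases (default 300, the read-length scale).
#' @param samples sample ids fixing matrix row order (default: union seen in
#'   the primary records, sorted).
#' @return list with `callset` (merged [VariantCallSet] on primary
#'   coordinates) and `panel` ([FrequencyPanel]).
#' @export
callMtPanel <- function(primaryRecords, shiftedRecords, L, shift = 10000,
                        edgeMargin = 300, samples = NULL) {
  prim <- data.table::as.data.table(primaryRecords)
  shif <- data.table::as.data.table(shiftedRecords)
  if (any(stats::na.omit(c(prim$ploidy, shif$ploidy)) != 1))
    stop("ploidy-conflict error: mitochondrial records must be haploid")
  if (is.null(samples))
    samples <- sort(unique(c(prim$sample, shif$sample)))
  mt <- unique(prim$contig)
  if (length(mt) != 1) stop("records must live on one mitochondrial contig")
  sexes <- stats::setNames(rep("female", length(samples)), samples)
  pmap <- PloidyMap(sexes, NULL, "TWO_PAR")
  csP <- jointGenotypeRegion(prim, Region(mt, 1, L), pmap, category = "mito",
                             samples = samples)
  shif$contig <- mt
  csS <- jointGenotypeRegion(shif, Region(mt, 1, L), pmap, category = "mito",
                             samples = samples)
  # express the shifted call set in primary coordinates
  csS@sites$pos <- as.integer(mtRemap(csS@sites$pos, L, shift))
  ordS <- order(csS@sites$pos)
  csS <- callsetSubset(csS, ordS)
  swap <- function(p) p <= edgeMargin | p > L - edgeMargin
  keepP <- which(!swap(csP@sites$pos))
  keepS <- which(swap(csS@sites$pos))
  merged <- callsetBind(list(callsetSubset(csP, keepP),
                             callsetSubset(csS, keepS)))
  dup <- duplicated(merged@sites$pos)
  if (any(dup)) merged <- callsetSubset(merged, which(!dup))
  list(callset = merged, panel = computeFrequencies(merged))
}
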