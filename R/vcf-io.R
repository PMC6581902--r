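# Reading per-sample VCFs and writing/reading the AC/AN/AF panel VCF.
# Parsing goes through vcfR; a light pre-scan supplies line-numbered errors
# for structurally broken files.

record_columns <- c("sample", "contig", "pos", "ref", "alt", "a1", "a2",
                    "ploidy", "dp", "ad", "adf", "adr", "pl", "gq")

# second-smallest PL minus smallest, the per-sample evidence weight used by
# the site QUAL proxy
.gq_from_pl <- function(pl) {
  vapply(strsplit(pl, ",", fixed = TRUE), function(v) {
    x <- suppressWarnings(sort(as.numeric(v)))
    if (length(x) < 2 || anyNA(x[1:2])) return(NA_real_)
    x[2] - x[1]
  }, numeric(1))
}

.parse_gt <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a1 <- a2 <- rep(NA_integer_, length(gt))
  ploidy <- rep(NA_integer_, length(gt))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ploidy[i] <- length(p)
    if (p[1] != ".") a1[i] <- as.integer(p[1])
    if (length(p) >= 2 && p[2] != ".") a2[i] <- as.integer(p[2])
    if (all(p == ".")) ploidy[i] <- NA_integer_
  }
  list(a1 = a1, a2 = a2, ploidy = ploidy)
}

#' Read a single-sample VCF into site records
#'
#' Returns one record per VCF data line with genotype (allele indices),
#' inferred ploidy (from GT arity), depth, per-allele depths, per-allele
#' strand counts and phred-scaled genotype likelihoods. Missing optional
#' FORMAT fields are populated as NA. Records are returned in file coordinate
#' order (the pipeline requires coordinate-sorted input).
#'
#' @param path VCF path.
#' @param sampleId expected sample id; a mismatch with the file's sample
#'   column is an identity error.
#' @return a data.table with columns sample, contig, pos, ref, alt, a1, a2,
#'   ploidy, dp, ad, adf, adr, pl, gq.
#' @export
readSampleVcf <- function(path, sampleId = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  for (i in body_idx) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 10)
      stop(sprintf("malformed VCF line %d: expected >= 10 fields, got %d",
                   i, nf))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  smp <- colnames(v@gt)[-1]
  if (length(smp) != 1) stop("expected a single-sample VCF")
  if (!is.null(sampleId) && smp != sampleId)
    stop(sprintf("sample-id mismatch: file has '%s', expected '%s'",
                 smp, sampleId))
  fx <- v@fix
  n <- nrow(fx)
  ex <- function(el) {
    m <- vcfR::extract.gt(v, element = el)
    if (is.null(m)) rep(NA_character_, n) else as.character(m[, 1])
  }
  gtv <- ex("GT")
  if (all(is.na(gtv))) stop("VCF has no GT field")
  g <- .parse_gt(gtv)
  plv <- ex("PL")
  alt <- as.character(fx[, "ALT"])
  alt[is.na(alt) | alt == "."] <- ""
  rec <- data.table::data.table(
    sample = smp, contig = as.character(fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]), ref = as.character(fx[, "REF"]),
    alt = alt, a1 = g$a1, a2 = g$a2, ploidy = g$ploidy,
    dp = suppressWarnings(as.integer(ex("DP"))),
    ad = ex("AD"), adf = ex("ADF"), adr = ex("ADR"),
    pl = plv, gq = .gq_from_pl(plv))
  nalt <- ifelse(rec$alt == "", 0L,
                 lengths(strsplit(rec$alt, ",", fixed = TRUE)))
  bad <- which(pmax(rec$a1, rec$a2, na.rm = TRUE) > nalt &
                 !(is.na(rec$a1) & is.na(rec$a2)))
  if (length(bad))
    stop(sprintf("genotype allele index out of range at %s:%d",
                 rec$contig[bad[1]], rec$pos[bad[1]]))
  rec
}

#' Write site records as a single-sample VCF
#'
#' Inverse of [readSampleVcf()]; used by the synthetic cohort generator.
#'
#' @param records record table (see [readSampleVcf()] for the schema).
#' @param path output path.
#' @param contigLengths optional named vector for contig header lines.
#' @export
writeSampleVcf <- function(records, path, contigLengths = NULL) {
  smp <- unique(records$sample)
  if (length(smp) != 1) stop("records must belong to one sample")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelforge",
           if (!is.null(contigLengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                     as.integer(contigLengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward-strand allele depths\">",
           "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse-strand allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", smp), collapse = "\t"))
  gt <- ifelse(is.na(records$ploidy), "./.",
               ifelse(records$ploidy == 1,
                      ifelse(is.na(records$a1), ".", records$a1),
                      paste(ifelse(is.na(records$a1), ".", records$a1),
                            ifelse(is.na(records$a2), ".", records$a2),
                            sep = "/")))
  dotify <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))
  smp_col <- paste(gt, dotify(records$pl), dotify(records$dp),
                   dotify(records$ad), dotify(records$adf),
                   dotify(records$adr), sep = ":")
  body <- paste(records$contig, records$pos, ".", records$ref,
                ifelse(records$alt == "", ".", records$alt), ".", ".", ".",
                "GT:PL:DP:AD:ADF:ADR", smp_col, sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Write an allele frequency panel as VCF 4.2
#'
#' Emits one record per site with INFO fields `AC` (per ALT), `AN` and `AF`
#' (per ALT); multiallelic sites are written as one record with
#' comma-separated ALT alleles. Input must be coordinate-sorted within each
#' contig (contig blocks in order of first appearance).
#'
#' @param panel a [FrequencyPanel].
#' @param path output path.
#' @param contigLengths optional named vector for contig header lines.
#' @export
writePanelVcf <- function(panel, path, contigLengths = NULL) {
  e <- data.table::as.data.table(panelEntries(panel))
  if (nrow(e)) {
    ord <- order(match(e$contig, unique(e$contig)), e$pos, e$altIndex)
    if (!identical(ord, seq_len(nrow(e))))
      stop("ordering error: panel entries must be coordinate-sorted")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelforge",
           if (!is.null(contigLengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                     as.integer(contigLengths)),
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternative allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called allele number\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternative allele frequency\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  if (nrow(e) == 0) {
    writeLines(hdr, path)
    return(invisible(NULL))
  }
  pos <- NULL # data.table NSE
  site <- e[, list(alt = paste(alt, collapse = ","),
                   ac = paste(ac, collapse = ","),
                   an = an[1],
                   af = paste(sprintf("%.10g", af), collapse = ","),
                   filter = filter[1]),
            by = c("contig", "pos", "ref")]
  body <- paste(site$contig, site$pos, ".", site$ref, site$alt, ".",
                site$filter,
                sprintf("AC=%s;AN=%d;AF=%s", site$ac, as.integer(site$an),
                        site$af),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(NULL)
}

#' Read a panel VCF back into a FrequencyPanel
#'
#' AF is recomputed as AC/AN (exact), so a write/read round trip preserves
#' every field bit-for-bit.
#'
#' @param path panel VCF path.
#' @return a [FrequencyPanel]; `nSamples` is NA (not recorded in the file).
#' @export
readPanelVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (is.null(fx) || nrow(fx) == 0)
    return(new("FrequencyPanel", entries = empty_panel_entries(),
               nSamples = NA_real_))
  getin <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    sub(paste0("^;?", key, "="), "", m)
  }
  rows <- lapply(seq_len(nrow(fx)), function(i) {
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- fx[i, "INFO"]
    ac <- as.integer(strsplit(getin(info, "AC"), ",")[[1]])
    an <- as.integer(getin(info, "AN"))
    filt <- fx[i, "FILTER"]
    if (is.na(filt)) filt <- "PASS"
    data.frame(contig = fx[i, "CHROM"], pos = as.integer(fx[i, "POS"]),
               ref = fx[i, "REF"], alt = alts,
               altIndex = seq_along(alts), ac = ac, an = an,
               af = ifelse(an > 0, ac / an, 0),
               multiallelic = length(alts) > 1, filter = filt,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  new("FrequencyPanel", entries = entries, nSamples = NA_real_)
}

empty_panel_entries <- function() {
  data.frame(contig = character(0), pos = integer(0), ref = character(0),
             alt = character(0), altIndex = integer(0), ac = integer(0),
             an = integer(0), af = numeric(0), multiallelic = logical(0),
             filter = character(0), stringsAsFactors = FALSE)
}
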