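#' @import methods
#' @importFrom stats rbeta rbinom rnbinom runif rnorm setNames complete.cases
#'   cor dhyper kmeans prcomp
#' @importFrom utils head tail
#' @importFrom data.table data.table as.data.table rbindlist setkey setorder
#'   := .N .SD fread fwrite copy
NULL

setClassUnion("ANYOrNULL", c("NULL", "data.frame", "list"))

#' Genomic region (1-based, inclusive)
#'
#' A closed interval on a named contig. All coordinates in the package are
#' 1-based and inclusive, following VCF convention; BED input is converted at
#' the boundary.
#'
#' @slot contig contig name.
#' @slot start,end 1-based inclusive bounds, `start <= end`.
#' @export
setClass("Region", representation(contig = "character", start = "numeric",
                                  end = "numeric"))

setValidity("Region", function(object) {
  if (length(object@start) != 1 || length(object@end) != 1)
    return("start and end must be scalars")
  if (object@start < 1) return("start must be >= 1")
  if (object@end < object@start) return("end must be >= start")
  TRUE
})

#' @rdname Region-class
#' @param contig contig name.
#' @param start,end 1-based inclusive interval bounds.
#' @export
Region <- function(contig, start, end) {
  new("Region", contig = as.character(contig), start = as.numeric(start),
      end = as.numeric(end))
}

setMethod("show", "Region", function(object) {
  cat(sprintf("Region %s:%d-%d (%d bp)\n", object@contig,
              as.integer(object@start), as.integer(object@end),
              as.integer(object@end - object@start + 1)))
})

#' Named X-chromosome sub-regions and PAR convention
#'
#' Holds the PAR1, XTR and PAR2 intervals of the X chromosome together with
#' the pseudoautosomal convention in force: `"TWO_PAR"` treats only PAR1 and
#' PAR2 as diploid in males, `"THREE_PAR"` additionally treats the
#' X-transposed region (XTR) as pseudoautosomal.
#'
#' @slot par1,xtr,par2 [Region] objects on the X contig, strictly ordered and
#'   non-overlapping.
#' @slot mode `"TWO_PAR"` or `"THREE_PAR"`.
#' @export
setClass("XRegionMap", representation(par1 = "Region", xtr = "Region",
                                      par2 = "Region", mode = "character"))

setValidity("XRegionMap", function(object) {
  if (!object@mode %in% c("TWO_PAR", "THREE_PAR"))
    return("mode must be TWO_PAR or THREE_PAR")
  if (!(object@par1@end < object@xtr@start))
    return("PAR1 must end before XTR starts")
  if (!(object@xtr@end < object@par2@start))
    return("XTR must end before PAR2 starts")
  TRUE
})

#' @rdname XRegionMap-class
#' @param par1,xtr,par2 [Region] objects (or length-2 numeric `c(start, end)`
#'   vectors, taken to be on contig `"X"`).
#' @param mode pseudoautosomal convention, `"TWO_PAR"` or `"THREE_PAR"`.
#' @export
XRegionMap <- function(par1, xtr, par2, mode = "THREE_PAR") {
  as_region <- function(x) {
    if (is(x, "Region")) x else Region("X", x[1], x[2])
  }
  new("XRegionMap", par1 = as_region(par1), xtr = as_region(xtr),
      par2 = as_region(par2), mode = mode)
}

setMethod("show", "XRegionMap", function(object) {
  cat(sprintf("XRegionMap (%s)\n", object@mode))
  for (nm in c("par1", "xtr", "par2")) {
    r <- slot(object, nm)
    cat(sprintf("  %-5s %s:%d-%d\n", toupper(nm), r@contig,
                as.integer(r@start), as.integer(r@end)))
  }
})

#' Genome build: contigs plus X sub-region map
#'
#' Declares the contigs the pipeline operates on (name, length, circularity,
#' category) and, optionally, the X-chromosome sub-region map. Contig order is
#' the declared order and fixes chunking and merge order downstream.
#'
#' @slot contigs data.frame with columns `name`, `length`, `circular`,
#'   `category` (one of autosome/chrX/chrY/mito).
#' @slot xmap an [XRegionMap] or NULL.
#' @export
setClass("GenomeBuild", representation(contigs = "data.frame",
                                       xmap = "ANY"))

setValidity("GenomeBuild", function(object) {
  cc <- object@contigs
  need <- c("name", "length", "circular", "category")
  if (!all(need %in% names(cc))) return("contigs must have name/length/circular/category")
  if (any(cc$length < 1)) return("contig lengths must be >= 1")
  if (anyDuplicated(cc$name)) return("duplicate contig names")
  if (!all(cc$category %in% c("autosome", "chrX", "chrY", "mito")))
    return("category must be autosome, chrX, chrY or mito")
  if (any(cc$circular & cc$category != "mito"))
    return("only mito contigs may be circular")
  if (!is.null(object@xmap) && !is(object@xmap, "XRegionMap"))
    return("xmap must be an XRegionMap or NULL")
  TRUE
})

#' @rdname GenomeBuild-class
#' @param contigs data.frame with columns name, length, circular, category.
#' @param xmap optional [XRegionMap].
#' @export
GenomeBuild <- function(contigs, xmap = NULL) {
  new("GenomeBuild", contigs = as.data.frame(contigs), xmap = xmap)
}

#' @rdname GenomeBuild-class
#' @param x a GenomeBuild.
#' @export
contigs <- function(x) x@contigs

#' @rdname GenomeBuild-class
#' @export
xRegionMap <- function(x) x@xmap

setMethod("show", "GenomeBuild", function(object) {
  cat(sprintf("GenomeBuild with %d contig(s)\n", nrow(object@contigs)))
  print(object@contigs, row.names = FALSE)
  if (!is.null(object@xmap)) show(object@xmap)
})

#' Cohort-level variant call set
#'
#' The product of joint genotype aggregation over a region: one row of `sites`
#' per variant site (position with at least one alternative allele carried by
#' at least one sample), plus per-sample genotype, depth and ploidy matrices
#' (samples x sites). Genotype matrices `A1`/`A2` hold merged allele indices
#' (0 = REF, k = k-th ALT); `A2` is NA wherever the sample is haploid, and
#' both are NA for a no-call.
#'
#' @slot samples ordered sample ids (matrix row order).
#' @slot sites data.frame with columns contig, pos, ref, alt (comma-joined),
#'   nalt, qual, reffwd, refrev, altfwd, altrev, multiallelic.
#' @slot A1,A2,DP,PLOIDY integer matrices, samples x sites.
#' @export
setClass("VariantCallSet", representation(samples = "character",
                                          sites = "data.frame",
                                          A1 = "matrix", A2 = "matrix",
                                          DP = "matrix", PLOIDY = "matrix"))

setValidity("VariantCallSet", function(object) {
  ns <- length(object@samples)
  nv <- nrow(object@sites)
  for (m in c("A1", "A2", "DP", "PLOIDY")) {
    d <- dim(slot(object, m))
    if (!identical(d, c(ns, nv)))
      return(sprintf("%s must be %d x %d", m, ns, nv))
  }
  TRUE
})

setMethod("show", "VariantCallSet", function(object) {
  cat(sprintf("VariantCallSet: %d sample(s) x %d site(s)\n",
              length(object@samples), nrow(object@sites)))
  if (nrow(object@sites)) {
    cat(sprintf("  contigs: %s; multiallelic sites: %d\n",
                paste(unique(object@sites$contig), collapse = ","),
                sum(object@sites$multiallelic)))
  }
})

#' @rdname VariantCallSet-class
#' @param x a VariantCallSet.
#' @export
callsetSamples <- function(x) x@samples

#' @rdname VariantCallSet-class
#' @export
callsetSites <- function(x) x@sites

#' @rdname VariantCallSet-class
#' @export
nSites <- function(x) nrow(x@sites)

#' Allele frequency panel
#'
#' One row per (site, ALT allele): contig, pos, ref, alt, altIndex, ac
#' (alternative allele count), an (total called allele number at the site),
#' af = ac/an, multiallelic flag and filter status. Multiallelic sites are
#' retained and contribute one row per ALT.
#'
#' @slot entries the per-ALT table.
#' @slot nSamples number of samples the panel was computed from.
#' @export
setClass("FrequencyPanel", representation(entries = "data.frame",
                                          nSamples = "numeric"))

setValidity("FrequencyPanel", function(object) {
  e <- object@entries
  need <- c("contig", "pos", "ref", "alt", "altIndex", "ac", "an", "af",
            "multiallelic", "filter")
  if (!all(need %in% names(e))) return("missing panel entry columns")
  if (nrow(e)) {
    if (any(e$ac < 0) || any(e$an < 0)) return("negative AC/AN")
    bad <- e$an > 0 & abs(e$af - e$ac / e$an) > 1e-12
    if (any(bad)) return("af must equal ac/an where an > 0")
  }
  TRUE
})

setMethod("show", "FrequencyPanel", function(object) {
  e <- object@entries
  cat(sprintf("FrequencyPanel: %d entr%s over %d site(s), %d sample(s)\n",
              nrow(e), if (nrow(e) == 1) "y" else "ies",
              length(unique(paste(e$contig, e$pos))), object@nSamples))
})

#' @rdname FrequencyPanel-class
#' @param x a FrequencyPanel.
#' @export
panelEntries <- function(x) x@entries

#' Dosage genotype matrix
#'
#' Samples x variants matrix of alternative-allele dosages (0/1/2, NA for
#' missing) with variant identities, the interchange format of the
#' population-structure workflow.
#'
#' @slot dosage numeric matrix, samples x variants.
#' @slot variants data.frame with columns contig, pos, ref, alt.
#' @slot samples sample ids (row order).
#' @export
setClass("GenotypeMatrix", representation(dosage = "matrix",
                                          variants = "data.frame",
                                          samples = "character"))

setValidity("GenotypeMatrix", function(object) {
  if (nrow(object@dosage) != length(object@samples))
    return("dosage rows must match samples")
  if (ncol(object@dosage) != nrow(object@variants))
    return("dosage columns must match variants")
  d <- object@dosage
  if (!all(is.na(d) | d %in% 0:2)) return("dosages must be 0/1/2 or NA")
  TRUE
})

#' @rdname GenotypeMatrix-class
#' @param dosage samples x variants matrix of 0/1/2/NA.
#' @param variants data.frame with contig, pos, ref, alt.
#' @param samples sample ids.
#' @export
GenotypeMatrix <- function(dosage, variants, samples = rownames(dosage)) {
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  new("GenotypeMatrix", dosage = as.matrix(dosage),
      variants = as.data.frame(variants), samples = as.character(samples))
}

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sample(s) x %d variant(s); missing %.3f%%\n",
              nrow(object@dosage), ncol(object@dosage),
              100 * mean(is.na(object@dosage))))
})

#' @rdname GenotypeMatrix-class
#' @param x a GenotypeMatrix.
#' @export
dosages <- function(x) x@dosage

#' @rdname GenotypeMatrix-class
#' @export
gmVariants <- function(x) x@variants

#' @rdname GenotypeMatrix-class
#' @export
gmSamples <- function(x) x@samples

#' WGS vs array genotype concordance cross-tabulation
#'
#' 5x5 count matrix indexed by WGS state (rows) x array state (columns) over
#' the states NotObserved, NoCall, HomRef, Het, HomAlt. The
#' (NotObserved, NotObserved) cell is undefined and held as NA.
#'
#' @slot counts the 5x5 matrix.
#' @slot perSample optional named list of per-sample 5x5 matrices.
#' @export
setClass("ConcordanceMatrix", representation(counts = "matrix",
                                             perSample = "ANY"))

concordanceStates <- c("NotObserved", "NoCall", "HomRef", "Het", "HomAlt")

setValidity("ConcordanceMatrix", function(object) {
  if (!identical(dim(object@counts), c(5L, 5L))) return("counts must be 5x5")
  v <- object@counts
  v[1, 1] <- 0
  if (any(v < 0, na.rm = TRUE)) return("negative counts")
  TRUE
})

setMethod("show", "ConcordanceMatrix", function(object) {
  cat("ConcordanceMatrix (rows: WGS, cols: array)\n")
  print(object@counts)
})

#' @rdname ConcordanceMatrix-class
#' @param x a ConcordanceMatrix.
#' @export
concordanceCounts <- function(x) x@counts

#' Sex-aware ploidy resolver
#'
#' Resolves the expected ploidy of a (sample, contig category, position)
#' combination: females are diploid everywhere on the X; males are diploid in
#' PAR1/PAR2 (and XTR under the THREE_PAR convention) and haploid elsewhere on
#' the X; every sample is haploid on the mitochondrial genome; autosomes are
#' diploid.
#'
#' @slot sexes named character vector, values "male"/"female".
#' @slot xmap an [XRegionMap].
#' @slot mode pseudoautosomal convention used for resolution.
#' @export
setClass("PloidyMap", representation(sexes = "character", xmap = "ANY",
                                     mode = "character"))

setValidity("PloidyMap", function(object) {
  if (!all(object@sexes %in% c("male", "female")))
    return("sexes must be male/female (exclude ambiguous samples upstream)")
  if (is.null(names(object@sexes))) return("sexes must be named by sample id")
  if (!object@mode %in% c("TWO_PAR", "THREE_PAR")) return("bad mode")
  TRUE
})

#' @rdname PloidyMap-class
#' @param sexes named character vector of "male"/"female" per sample id.
#' @param xmap an [XRegionMap] (may be NULL if no X data are processed).
#' @param mode pseudoautosomal convention; defaults to the map's own mode.
#' @export
PloidyMap <- function(sexes, xmap = NULL, mode = NULL) {
  if (is.null(mode)) mode <- if (is.null(xmap)) "TWO_PAR" else xmap@mode
  new("PloidyMap", sexes = sexes, xmap = xmap, mode = mode)
}

setMethod("show", "PloidyMap", function(object) {
  cat(sprintf("PloidyMap: %d sample(s) (%d female, %d male), mode %s\n",
              length(object@sexes), sum(object@sexes == "female"),
              sum(object@sexes == "male"), object@mode))
})
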