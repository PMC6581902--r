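# Coordinate conventions, region arithmetic and genome configuration.
# Everything internal is 1-based inclusive (VCF convention); BED input is
# converted at the boundary.

#' Partition a contig into overlapping chunks
#'
#' Splits `[1, contigLength]` into chunks of `chunkSize` bases in which each
#' consecutive pair shares exactly `overlap` positions
#' (`start[k+1] = end[k] - overlap + 1`). The last chunk may be shorter; the
#' union always covers the whole contig. Used to bound the working set of the
#' joint genotyping step; the shared zones are re-checked for call concordance
#' when chunks are merged.
#'
#' @param contigLength contig length in bases.
#' @param chunkSize chunk size in bases (default 3 Mb).
#' @param overlap overlap between adjacent chunks in bases (default 1 kb);
#'   must be smaller than `chunkSize`.
#' @return data.frame with columns `start`, `end` (1-based inclusive), one row
#'   per chunk in coordinate order.
#' @export
partitionContig <- function(contigLength, chunkSize = 3e6, overlap = 1000) {
  contigLength <- as.numeric(contigLength)
  if (contigLength < 1) stop("contigLength must be >= 1")
  if (overlap < 0) stop("overlap must be >= 0")
  if (overlap >= chunkSize) stop("overlap must be smaller than chunkSize")
  starts <- ends <- numeric(0)
  s <- 1
  repeat {
    e <- min(s + chunkSize - 1, contigLength)
    starts <- c(starts, s)
    ends <- c(ends, e)
    if (e >= contigLength) break
    s <- e - overlap + 1
  }
  data.frame(start = starts, end = ends)
}

#' Region containment and intersection
#'
#' @param region a [Region].
#' @param pos positions to test (same contig assumed).
#' @return `regionContains`: logical vector; `regionIntersect`: the
#'   intersection [Region] or NULL when empty.
#' @export
regionContains <- function(region, pos) {
  pos >= region@start & pos <= region@end
}

#' @rdname regionContains
#' @param a,b [Region]s on the same contig.
#' @export
regionIntersect <- function(a, b) {
  if (a@contig != b@contig) return(NULL)
  s <- max(a@start, b@start)
  e <- min(a@end, b@end)
  if (s > e) return(NULL)
  Region(a@contig, s, e)
}

#' @rdname regionContains
#' @export
regionLength <- function(region) region@end - region@start + 1

#' Read a genome configuration file
#'
#' The configuration is a declarative YAML file listing contigs (name, length,
#' circular, category) and optionally the X sub-region coordinates:
#'
#' ```yaml
#' contigs:
#'   - {name: "1", length: 10000000, circular: false, category: autosome}
#'   - {name: "X", length: 155270560, circular: false, category: chrX}
#'   - {name: "MT", length: 16569, circular: true, category: mito}
#' x_regions:
#'   par1: [60001, 2699520]
#'   xtr:  [88456802, 92375509]
#'   par2: [154931044, 155260560]
#'   mode: THREE_PAR
#' ```
#'
#' @param path path to the YAML file.
#' @return a [GenomeBuild].
#' @export
readGenomeConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$contigs)) stop("genome config must declare contigs")
  cc <- do.call(rbind, lapply(cfg$contigs, function(ct) {
    data.frame(name = as.character(ct$name), length = as.numeric(ct$length),
               circular = isTRUE(ct$circular),
               category = as.character(ct$category))
  }))
  xmap <- NULL
  if (!is.null(cfg$x_regions)) {
    xr <- cfg$x_regions
    xname <- cc$name[cc$category == "chrX"][1]
    if (is.na(xname)) xname <- "X"
    xmap <- XRegionMap(Region(xname, xr$par1[1], xr$par1[2]),
                       Region(xname, xr$xtr[1], xr$xtr[2]),
                       Region(xname, xr$par2[1], xr$par2[2]),
                       mode = if (is.null(xr$mode)) "THREE_PAR" else xr$mode)
  }
  GenomeBuild(cc, xmap)
}

#' GRCh37 X sub-region preset
#'
#' The full-scale GRCh37 coordinates of PAR1 (60,001-2,699,520), XTR
#' (88,456,802-92,375,509) and PAR2 (154,931,044-155,260,560) on the X
#' chromosome.
#'
#' @param mode pseudoautosomal convention for the returned map.
#' @return an [XRegionMap].
#' @export
grch37XRegionMap <- function(mode = "THREE_PAR") {
  XRegionMap(Region("X", 60001, 2699520),
             Region("X", 88456802, 92375509),
             Region("X", 154931044, 155260560), mode = mode)
}

#' Scaled-down X sub-region preset
#'
#' The GRCh37 coordinates divided by `scale` (default 1/100), so that
#' synthetic X contigs with the same proportional layout run in seconds.
#'
#' @param scale integer divisor applied to the full-scale coordinates.
#' @param mode pseudoautosomal convention.
#' @return an [XRegionMap]; the implied contig length is
#'   `scaledXLength(scale)`.
#' @export
scaledXRegionMap <- function(scale = 100, mode = "THREE_PAR") {
  sc <- function(x) pmax(1, ceiling(x / scale))
  XRegionMap(Region("X", sc(60001), sc(2699520)),
             Region("X", sc(88456802), sc(92375509)),
             Region("X", sc(154931044), sc(155260560)), mode = mode)
}

#' @rdname scaledXRegionMap
#' @export
scaledXLength <- function(scale = 100) ceiling(155270560 / scale)

#' Read BED intervals as 1-based inclusive regions
#'
#' Converts the BED 0-based half-open convention to the package's 1-based
#' inclusive convention at the boundary.
#'
#' @param path BED file path (first three columns used, optional fourth as
#'   name).
#' @return data.frame with columns contig, start, end, name.
#' @export
readBedRegions <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(contig = as.character(bed[[1]]),
                    start = as.numeric(bed[[2]]) + 1,
                    end = as.numeric(bed[[3]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    paste0("region", seq_len(nrow(bed)))
  out
}

#' Write regions as BED (inverse boundary conversion)
#'
#' @param regions data.frame with contig, start, end (1-based inclusive) and
#'   optionally name.
#' @param path output path.
#' @export
writeBedRegions <- function(regions, path) {
  df <- data.frame(regions$contig, as.integer(regions$start) - 1L,
                   as.integer(regions$end))
  if (!is.null(regions$name)) df$name <- regions$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
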