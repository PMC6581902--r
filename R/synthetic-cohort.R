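# Seeded synthetic cohort generator: Beta-distributed population allele
# frequencies, Hardy-Weinberg genotypes, sex-linked ploidy, Mendelian
# relatives and duplicates, genotyping error and no-calls on an array marker
# subset, negative-binomial depth with a MAPQ-0 mixture, and per-allele
# strand counts. Every stage of the panel pipeline is testable from these
# outputs without any external data.

#' Synthetic cohort specification
#'
#' Describes the miniature cohort to generate. Defaults are the package's
#' reference study conditions: a 100-sample, half-female cohort on one 1 Mb
#' autosome, a 1/100-scale X chromosome with the proportional PAR1/XTR/PAR2
#' layout, and the full-length (16,569 b) mitochondrial genome; allele
#' frequencies from Beta(1, 3) (a low-frequency-skewed site spectrum);
#' 1% symmetric genotyping error on sequencing and array genotypes; half of
#' the sites carried on the array with a 1% no-call rate; 30x mean depth with
#' mild negative-binomial overdispersion.
#'
#' @slot nSamples number of samples (>= 2).
#' @slot sexRatio fraction of female samples.
#' @slot contigPlan data.frame with name, category, length.
#' @slot nSitesPerContig variant sites simulated per contig.
#' @slot afAlpha,afBeta Beta prior parameters for population allele
#'   frequencies.
#' @slot errorRate symmetric single-step genotype flip probability
#'   (hom <-> het) in the sequencing records.
#' @slot arrayErrorRate the same flip probability for array genotypes.
#' @slot arrayMarkerFraction fraction of (non-mitochondrial) sites carried
#'   on the array.
#' @slot arrayNoCallRate per-entry array no-call probability.
#' @slot relativePlan data.frame with relationship (duplicate,
#'   parent_offspring, full_sibling, second_degree, third_degree) and count.
#' @slot depthMean,depthOverdispersion negative-binomial depth model (the
#'   overdispersion is 1/size; 0 means Poisson).
#' @slot mapq0Fraction,mapq0Repeat per-base probability that a read is
#'   MAPQ 0, outside and inside designated repeat bases.
#' @slot repeatFraction fraction of depth-track bases designated repeat.
#' @slot depthTrackBases span of the per-base depth track.
#' @slot dropoutRate probability that a sample has no record at a site.
#' @slot plScale phred distance between the best and next genotype
#'   likelihood.
#' @slot xtrDiploid if TRUE (default), male XTR truth behaves diploid, the
#'   pseudoautosomal-like behaviour the heterozygosity scan detects.
#' @slot xmap the [XRegionMap] used for truth ploidy (scaled preset by
#'   default).
#' @slot seed integer RNG seed; identical specs generate byte-identical
#'   output.
#' @export
setClass("CohortSpec", representation(
  nSamples = "numeric", sexRatio = "numeric", contigPlan = "data.frame",
  nSitesPerContig = "numeric", afAlpha = "numeric", afBeta = "numeric",
  errorRate = "numeric", arrayErrorRate = "numeric",
  arrayMarkerFraction = "numeric", arrayNoCallRate = "numeric",
  relativePlan = "data.frame", depthMean = "numeric",
  depthOverdispersion = "numeric", mapq0Fraction = "numeric",
  mapq0Repeat = "numeric", repeatFraction = "numeric",
  depthTrackBases = "numeric", dropoutRate = "numeric", plScale = "numeric",
  xtrDiploid = "logical", xmap = "ANY", seed = "numeric"))

setValidity("CohortSpec", function(object) {
  pr <- c(object@sexRatio, object@errorRate, object@arrayErrorRate,
          object@arrayMarkerFraction, object@arrayNoCallRate,
          object@mapq0Fraction, object@mapq0Repeat, object@repeatFraction,
          object@dropoutRate)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@nSamples < 2) return("nSamples must be >= 2")
  if (any(object@contigPlan$length < 100))
    return("contig lengths must be >= 100")
  if (!all(c("name", "category", "length") %in% names(object@contigPlan)))
    return("contigPlan needs name/category/length")
  TRUE
})

#' @rdname CohortSpec-class
#' @param nSamples,sexRatio,contigPlan,nSitesPerContig,afAlpha,afBeta,errorRate,arrayErrorRate,arrayMarkerFraction,arrayNoCallRate,relativePlan,depthMean,depthOverdispersion,mapq0Fraction,mapq0Repeat,repeatFraction,depthTrackBases,dropoutRate,plScale,xtrDiploid,xmap,seed see slot documentation.
#' @export
cohortSpec <- function(nSamples = 100, sexRatio = 0.5,
                       contigPlan = NULL, nSitesPerContig = 500,
                       afAlpha = 1, afBeta = 3, errorRate = 0.01,
                       arrayErrorRate = 0.01, arrayMarkerFraction = 0.5,
                       arrayNoCallRate = 0.01, relativePlan = NULL,
                       depthMean = 30, depthOverdispersion = 0.1,
                       mapq0Fraction = 0.01, mapq0Repeat = 0.5,
                       repeatFraction = 0.05, depthTrackBases = 10000,
                       dropoutRate = 0, plScale = 30, xtrDiploid = TRUE,
                       xmap = NULL, seed = 1) {
  if (is.null(contigPlan))
    contigPlan <- data.frame(
      name = c("1", "X", "MT"), category = c("autosome", "chrX", "mito"),
      length = c(1e6, scaledXLength(100), 16569), stringsAsFactors = FALSE)
  if (is.null(relativePlan))
    relativePlan <- data.frame(relationship = character(0),
                               count = integer(0), stringsAsFactors = FALSE)
  if (is.null(xmap)) xmap <- scaledXRegionMap(100)
  new("CohortSpec", nSamples = nSamples, sexRatio = sexRatio,
      contigPlan = contigPlan, nSitesPerContig = nSitesPerContig,
      afAlpha = afAlpha, afBeta = afBeta, errorRate = errorRate,
      arrayErrorRate = arrayErrorRate,
      arrayMarkerFraction = arrayMarkerFraction,
      arrayNoCallRate = arrayNoCallRate, relativePlan = relativePlan,
      depthMean = depthMean, depthOverdispersion = depthOverdispersion,
      mapq0Fraction = mapq0Fraction, mapq0Repeat = mapq0Repeat,
      repeatFraction = repeatFraction, depthTrackBases = depthTrackBases,
      dropoutRate = dropoutRate, plScale = plScale, xtrDiploid = xtrDiploid,
      xmap = xmap, seed = seed)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d samples (%.0f%% female), %d contig(s), seed %d\n",
              object@nSamples, 100 * object@sexRatio,
              nrow(object@contigPlan), as.integer(object@seed)))
})

#' Simulated cohort truth
#'
#' The ground truth generated from a [CohortSpec]: site list with true
#' allele frequencies, per-sample true genotypes (allele-index matrices, NA
#' second allele in haploid contexts), sample sexes and pedigree links.
#'
#' @slot spec the generating [CohortSpec].
#' @slot samples data.frame: id, sex, role, relatedTo.
#' @slot sites data.frame: contig, category, pos, ref, alt, af, xclass,
#'   maleDiploid.
#' @slot A1,A2 true genotype matrices (samples x sites).
#' @slot yDepthRatio,autoDepth per-sample Y/autosome mean-depth evidence.
#' @export
setClass("CohortTruth", representation(
  spec = "CohortSpec", samples = "data.frame", sites = "data.frame",
  A1 = "matrix", A2 = "matrix", yDepthRatio = "numeric",
  autoDepth = "numeric"))

setMethod("show", "CohortTruth", function(object) {
  cat(sprintf("CohortTruth: %d samples x %d sites (%s)\n",
              nrow(object@samples), nrow(object@sites),
              paste(sprintf("%s:%d", unique(object@sites$contig),
                            as.vector(table(factor(object@sites$contig,
                              levels = unique(object@sites$contig))))),
                    collapse = ", ")))
})

#' @rdname CohortTruth-class
#' @param x a CohortTruth.
#' @export
truthSamples <- function(x) x@samples

#' @rdname CohortTruth-class
#' @export
truthSites <- function(x) x@sites

#' @rdname CohortTruth-class
#' @export
truthSexes <- function(x) stats::setNames(x@samples$sex, x@samples$id)

.draw_alleles <- function(af, n) {
  matrix(stats::rbinom(n * length(af), 1, rep(af, each = n)), n,
         length(af), byrow = FALSE)
}

#' Simulate cohort truth
#'
#' Draws Hardy-Weinberg genotypes from Beta-distributed site allele
#' frequencies: two independent allele draws per sample in diploid contexts
#' (autosomes, female X, male pseudoautosomal X) and one draw in haploid
#' contexts (male non-PAR X, all mitochondria). Relatives from the plan then
#' overwrite the tail samples: duplicates are exact copies, children of
#' parent-offspring and sibling links receive one allele from each parent
#' (Mendelian, with X and mitochondrial transmission following the sexes),
#' and second/third-degree relatives share one allele identical-by-descent
#' at 50%/25% of autosomal sites. Identical specs (including seed) give
#' byte-identical output.
#'
#' @param spec a [CohortSpec].
#' @return a [CohortTruth].
#' @export
simulateTruth <- function(spec) {
  set.seed(spec@seed)
  n <- spec@nSamples
  ids <- sprintf("S%0*d", max(3, nchar(n)), seq_len(n))
  nF <- round(n * spec@sexRatio)
  sex <- sample(c(rep("female", nF), rep("male", n - nF)))

  # site list
  sites_list <- lapply(seq_len(nrow(spec@contigPlan)), function(ci) {
    ct <- spec@contigPlan[ci, ]
    ns <- min(spec@nSitesPerContig, ct$length)
    pos <- sort(sample.int(ct$length, ns))
    ref <- sample(c("A", "C", "G", "T"), ns, replace = TRUE)
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    is_ts <- stats::runif(ns) < 2 / 3
    alt <- ifelse(is_ts, transition[ref],
                  vapply(ref, function(r)
                    sample(transversions[[r]], 1), character(1)))
    data.frame(contig = ct$name, category = ct$category, pos = pos,
               ref = ref, alt = unname(alt),
               af = stats::rbeta(ns, spec@afAlpha, spec@afBeta),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  sites$xclass <- "NA"
  isx <- sites$category == "chrX"
  if (any(isx))
    sites$xclass[isx] <- classifyXRegion(sites$pos[isx], spec@xmap,
                                         mode = "THREE_PAR")
  sites$maleDiploid <- isx & (sites$xclass %in% c("PAR1", "PAR2") |
                                (sites$xclass == "XTR" & spec@xtrDiploid))
  S <- nrow(sites)

  # founder genotypes (everyone drawn as founder first)
  A1 <- .draw_alleles(sites$af, n)
  A2 <- .draw_alleles(sites$af, n)
  male <- sex == "male"
  hap <- matrix(FALSE, n, S)
  hap[, sites$category == "mito"] <- TRUE
  xhap <- isx & !sites$maleDiploid
  hap[male, xhap] <- TRUE
  A2[hap] <- NA_integer_

  # relatives overwrite the tail
  role <- rep("founder", n)
  relatedTo <- rep(NA_character_, n)
  plan <- spec@relativePlan
  founder_cursor <- 1L
  tail_cursor <- n
  take_founders <- function(k) {
    idx <- founder_cursor:(founder_cursor + k - 1L)
    founder_cursor <<- founder_cursor + k
    idx
  }
  take_tail <- function(k) {
    idx <- tail_cursor:(tail_cursor - k + 1L)
    tail_cursor <<- tail_cursor - k
    idx
  }
  pick <- function(parent, cols) {
    use2 <- stats::runif(length(cols)) < 0.5 & !is.na(A2[parent, cols])
    ifelse(use2, A2[parent, cols], A1[parent, cols])
  }
  make_child <- function(child, father, mother) {
    auto <- which(sites$category == "autosome")
    A1[child, auto] <<- pick(father, auto)
    A2[child, auto] <<- pick(mother, auto)
    mito <- which(sites$category == "mito")
    A1[child, mito] <<- A1[mother, mito]
    A2[child, mito] <<- NA_integer_
    xs <- which(isx)
    if (length(xs)) {
      if (sex[child] == "male") {
        dip <- xs[sites$maleDiploid[xs]]
        nonp <- setdiff(xs, dip)
        A1[child, nonp] <<- pick(mother, nonp)
        A2[child, nonp] <<- NA_integer_
        if (length(dip)) {
          A1[child, dip] <<- pick(father, dip)
          A2[child, dip] <<- pick(mother, dip)
        }
      } else {
        A1[child, xs] <<- pick(father, xs)
        A2[child, xs] <<- pick(mother, xs)
      }
    }
  }
  for (pi in seq_len(nrow(plan))) {
    rel <- plan$relationship[pi]
    for (k in seq_len(plan$count[pi])) {
      if (founder_cursor > tail_cursor)
        stop("spec error: relative plan requires more founders than samples")
      if (rel == "duplicate") {
        src <- take_founders(1)
        dup <- take_tail(1)
        sex[dup] <- sex[src]
        A1[dup, ] <- A1[src, ]
        A2[dup, ] <- A2[src, ]
        role[dup] <- "duplicate"
        relatedTo[dup] <- ids[src]
      } else if (rel == "parent_offspring") {
        par <- take_founders(2)
        sex[par[1]] <- "male"
        sex[par[2]] <- "female"
        child <- take_tail(1)
        make_child(child, par[1], par[2])
        role[child] <- "child"
        relatedTo[child] <- paste(ids[par], collapse = ",")
      } else if (rel == "full_sibling") {
        par <- take_founders(2)
        sex[par[1]] <- "male"
        sex[par[2]] <- "female"
        sibs <- take_tail(2)
        for (sb in sibs) {
          make_child(sb, par[1], par[2])
          role[sb] <- "sibling"
          relatedTo[sb] <- paste(ids[par], collapse = ",")
        }
      } else if (rel %in% c("second_degree", "third_degree")) {
        src <- take_founders(1)
        relv <- take_tail(1)
        z1 <- if (rel == "second_degree") 0.5 else 0.25
        auto <- which(sites$category == "autosome")
        share <- stats::runif(length(auto)) < z1
        A1[relv, auto[share]] <- pick(src, auto[share])
        role[relv] <- rel
        relatedTo[relv] <- ids[src]
      } else stop(sprintf("unknown relationship '%s'", rel))
    }
  }
  # sexes may have been forced; refresh haploidy accordingly
  male <- sex == "male"
  hap <- matrix(FALSE, n, S)
  hap[, sites$category == "mito"] <- TRUE
  hap[male, xhap] <- TRUE
  A2[hap] <- NA_integer_
  # females reassigned from male founders need a second X allele
  needs2 <- is.na(A2) & !hap
  if (any(needs2)) {
    idx <- which(needs2, arr.ind = TRUE)
    A2[needs2] <- stats::rbinom(nrow(idx), 1, sites$af[idx[, 2]])
  }

  ydr <- ifelse(male, pmax(0, stats::rnorm(n, 0.5, 0.02)),
                pmax(0, stats::rnorm(n, 0.005, 0.002)))
  adp <- pmax(1, stats::rnorm(n, spec@depthMean, spec@depthMean * 0.05))
  new("CohortTruth", spec = spec,
      samples = data.frame(id = ids, sex = sex, role = role,
                           relatedTo = relatedTo, stringsAsFactors = FALSE),
      sites = sites, A1 = A1, A2 = A2, yDepthRatio = ydr, autoDepth = adp)
}

# single-step symmetric genotype error on allele-index matrices
.flip_genotypes <- function(a1, a2, hap, e) {
  if (e <= 0) return(list(a1 = a1, a2 = a2))
  flip <- matrix(stats::runif(length(a1)) < e, nrow(a1), ncol(a1))
  # haploid: allele toggles 0 <-> 1
  h <- flip & hap & !is.na(a1)
  a1[h] <- 1L - a1[h]
  # diploid: hom -> het, het -> one of the homs
  d <- flip & !hap & !is.na(a1)
  dose <- a1 + a2
  toHet <- d & (dose == 0L | dose == 2L)
  a1[toHet] <- 0L
  a2[toHet] <- 1L
  fromHet <- d & dose == 1L
  if (any(fromHet)) {
    toAlt <- stats::runif(sum(fromHet)) < 0.5
    a1[fromHet] <- as.integer(toAlt)
    a2[fromHet] <- as.integer(toAlt)
  }
  list(a1 = a1, a2 = a2)
}

#' Generate per-sample sequencing records from the truth
#'
#' Applies the symmetric single-step genotype error model, draws
#' negative-binomial depths, splits allele and strand counts binomially, and
#' attaches phred-scaled likelihood vectors (0 at the observed genotype,
#' `plScale` steps elsewhere). With `bqsrLike = TRUE` the non-minimal PL
#' entries are perturbed by a small positive jitter that never changes the
#' likelihood argmax — emulating a base-quality recalibration step whose
#' effect on genotype calls is nil.
#'
#' @param truth a [CohortTruth].
#' @param bqsrLike perturb PL values without changing genotypes.
#' @return named list (one record table per sample, [readSampleVcf()]
#'   schema).
#' @export
cohortRecords <- function(truth, bqsrLike = FALSE) {
  spec <- truth@spec
  set.seed(spec@seed + 1)
  n <- nrow(truth@samples)
  S <- nrow(truth@sites)
  hap <- is.na(truth@A2)
  obs <- .flip_genotypes(truth@A1, truth@A2, hap, spec@errorRate)
  keep <- if (spec@dropoutRate > 0)
    matrix(stats::runif(n * S) >= spec@dropoutRate, n, S) else
      matrix(TRUE, n, S)

  size <- if (spec@depthOverdispersion > 0) 1 / spec@depthOverdispersion
  dp <- if (is.null(size))
    matrix(stats::rpois(n * S, spec@depthMean), n, S) else
      matrix(stats::rnbinom(n * S, mu = spec@depthMean, size = size), n, S)

  a1 <- obs$a1
  a2 <- obs$a2
  dose <- ifelse(hap, a1 * 2L, a1 + a2) # 0..2 scale, hom alt = 2
  adAlt <- matrix(0L, n, S)
  hom_alt <- !is.na(dose) & dose == 2L
  adAlt[hom_alt] <- dp[hom_alt]
  het <- !is.na(dose) & dose == 1L
  adAlt[het] <- stats::rbinom(sum(het), dp[het], 0.5)
  adRef <- dp - adAlt
  adfR <- matrix(stats::rbinom(n * S, as.vector(adRef), 0.5), n, S)
  adfA <- matrix(stats::rbinom(n * S, as.vector(adAlt), 0.5), n, S)

  s <- spec@plScale
  jit <- function(k) if (bqsrLike) k else 0L
  if (bqsrLike) set.seed(spec@seed + 4)
  j1 <- if (bqsrLike) matrix(sample(1:5, n * S, replace = TRUE), n, S) else
    matrix(0L, n, S)
  j2 <- if (bqsrLike) matrix(sample(1:5, n * S, replace = TRUE), n, S) else
    matrix(0L, n, S)
  pl <- matrix(NA_character_, n, S)
  gq <- matrix(NA_real_, n, S)
  hp <- hap & !is.na(a1)
  pl[hp & a1 == 0L] <- paste0("0,", s + j1[hp & a1 == 0L])
  pl[hp & a1 == 1L] <- paste0(s + j1[hp & a1 == 1L], ",0")
  d0 <- !hap & !is.na(dose) & dose == 0L
  d1 <- !hap & !is.na(dose) & dose == 1L
  d2 <- !hap & !is.na(dose) & dose == 2L
  pl[d0] <- paste0("0,", s + j1[d0], ",", 2 * s + j2[d0])
  pl[d1] <- paste0(s + j1[d1], ",0,", s + j2[d1])
  pl[d2] <- paste0(2 * s + j2[d2], ",", s + j1[d2], ",0")
  gq[!is.na(a1)] <- s + pmin(j1, j2)[!is.na(a1)]

  ids <- truth@samples$id
  out <- vector("list", n)
  names(out) <- ids
  st <- truth@sites
  for (i in seq_len(n)) {
    sel <- which(keep[i, ])
    out[[i]] <- data.table::data.table(
      sample = ids[i], contig = st$contig[sel], pos = st$pos[sel],
      ref = st$ref[sel], alt = st$alt[sel], a1 = a1[i, sel],
      a2 = a2[i, sel],
      ploidy = ifelse(hap[i, sel], 1L, 2L),
      dp = dp[i, sel],
      ad = paste(adRef[i, sel], adAlt[i, sel], sep = ","),
      adf = paste(adfR[i, sel], adfA[i, sel], sep = ","),
      adr = paste(adRef[i, sel] - adfR[i, sel],
                  adAlt[i, sel] - adfA[i, sel], sep = ","),
      pl = pl[i, sel], gq = gq[i, sel])
  }
  out
}

#' Write the cohort's per-sample VCF files
#'
#' @param truth a [CohortTruth].
#' @param dir output directory (created if needed).
#' @param bqsrLike see [cohortRecords()].
#' @return invisible vector of file paths.
#' @export
emitSampleVcfs <- function(truth, dir, bqsrLike = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  recs <- cohortRecords(truth, bqsrLike = bqsrLike)
  lens <- stats::setNames(truth@spec@contigPlan$length,
                          truth@spec@contigPlan$name)
  paths <- character(length(recs))
  for (i in seq_along(recs)) {
    paths[i] <- file.path(dir, paste0(names(recs)[i], ".vcf"))
    writeSampleVcf(recs[[i]], paths[i], contigLengths = lens)
  }
  invisible(paths)
}

#' Generate the array genotype table
#'
#' A random fraction of the non-mitochondrial sites becomes the marker set;
#' entries are the true genotypes passed through independent flip-error and
#' no-call processes. Haploid truth (male non-PAR X) is reported as a
#' homozygous diploid genotype, as SNP arrays do.
#'
#' @param truth a [CohortTruth].
#' @return data.table: contig, pos, ref, alt, then one column per sample
#'   with values 0/0, 0/1, 1/1 or NoCall.
#' @export
emitArrayGenotypes <- function(truth) {
  spec <- truth@spec
  set.seed(spec@seed + 2)
  eligible <- which(truth@sites$category != "mito")
  markers <- eligible[stats::runif(length(eligible)) <
                        spec@arrayMarkerFraction]
  n <- nrow(truth@samples)
  hap <- is.na(truth@A2)[, markers, drop = FALSE]
  obs <- .flip_genotypes(truth@A1[, markers, drop = FALSE],
                         truth@A2[, markers, drop = FALSE], hap,
                         spec@arrayErrorRate)
  dose <- ifelse(hap, obs$a1 * 2L, obs$a1 + obs$a2)
  gt <- matrix(c("0/0", "0/1", "1/1")[dose + 1L], n, length(markers))
  if (spec@arrayNoCallRate > 0)
    gt[matrix(stats::runif(n * length(markers)) < spec@arrayNoCallRate,
              n, length(markers))] <- "NoCall"
  st <- truth@sites[markers, , drop = FALSE]
  out <- data.table::data.table(contig = st$contig, pos = st$pos,
                                ref = st$ref, alt = st$alt)
  for (i in seq_len(n)) out[[truth@samples$id[i]]] <- gt[i, ]
  out
}

#' Generate per-sample per-base depth track pairs
#'
#' For a span of `depthTrackBases` bases on the first contig, draws all-read
#' depth from the negative-binomial model and thins it binomially to the
#' MAPQ >= 20 track; a designated random `repeatFraction` of bases gets the
#' elevated `mapq0Repeat` thinning probability, so the difference between
#' the two tracks is elevated exactly on the repeat set.
#'
#' @param truth a [CohortTruth].
#' @return list: `tracks` (named list of `cbind(all, mq20)` matrices),
#'   `repeatMask` (logical per base), `contig`, `start`.
#' @export
emitDepthTracks <- function(truth) {
  spec <- truth@spec
  set.seed(spec@seed + 3)
  nb <- min(spec@depthTrackBases, spec@contigPlan$length[1])
  rep_mask <- stats::runif(nb) < spec@repeatFraction
  frac <- ifelse(rep_mask, spec@mapq0Repeat, spec@mapq0Fraction)
  size <- if (spec@depthOverdispersion > 0) 1 / spec@depthOverdispersion
  tracks <- lapply(seq_len(nrow(truth@samples)), function(i) {
    all <- if (is.null(size)) stats::rpois(nb, spec@depthMean) else
      stats::rnbinom(nb, mu = spec@depthMean, size = size)
    mq20 <- stats::rbinom(nb, all, 1 - frac)
    cbind(all = all, mq20 = mq20)
  })
  names(tracks) <- truth@samples$id
  list(tracks = tracks, repeatMask = rep_mask,
       contig = spec@contigPlan$name[1], start = 1)
}

#' Noise-free call set straight from the truth
#'
#' Builds a [VariantCallSet] from the true genotypes (no error, no
#' dropout), for tests and comparisons that need the zero-noise limit
#' without the record-emission step. Depth and strand fields are filled with
#' the model mean.
#'
#' @param truth a [CohortTruth].
#' @param categories contig categories to keep (default all).
#' @return a [VariantCallSet].
#' @export
truthCallSet <- function(truth, categories = NULL) {
  st <- truth@sites
  keep <- if (is.null(categories)) seq_len(nrow(st)) else
    which(st$category %in% categories)
  keep <- keep[order(match(st$contig[keep], unique(st$contig)),
                     st$pos[keep])]
  carrier <- colSums(truth@A1[, keep, drop = FALSE] > 0, na.rm = TRUE) +
    colSums(truth@A2[, keep, drop = FALSE] > 0, na.rm = TRUE) > 0
  keep <- keep[carrier]
  A1 <- truth@A1[, keep, drop = FALSE]
  A2 <- truth@A2[, keep, drop = FALSE]
  dpm <- matrix(as.integer(round(truth@spec@depthMean)), nrow(A1), ncol(A1))
  ploidy <- matrix(2L, nrow(A1), ncol(A1))
  ploidy[is.na(A2)] <- 1L
  sites <- data.frame(contig = st$contig[keep], pos = st$pos[keep],
                      ref = st$ref[keep], alt = st$alt[keep], nalt = 1L,
                      qual = 0, reffwd = 0, refrev = 0, altfwd = 0,
                      altrev = 0, multiallelic = FALSE,
                      stringsAsFactors = FALSE)
  new("VariantCallSet", samples = truth@samples$id, sites = sites, A1 = A1,
      A2 = A2, DP = dpm, PLOIDY = ploidy)
}

#' Redraw an independent cohort over the same sites
#'
#' Returns a new truth with the same site list and allele frequencies but a
#' fresh, unrelated sample draw — two such truths are independent samplings
#' from one population, the setting of the cross-panel comparison check.
#'
#' @param truth a [CohortTruth].
#' @param seed seed for the new draw.
#' @param nSamples optional new cohort size.
#' @return a [CohortTruth].
#' @export
resampleGenotypes <- function(truth, seed, nSamples = NULL) {
  spec <- truth@spec
  if (is.null(nSamples)) nSamples <- spec@nSamples
  set.seed(seed)
  n <- nSamples
  ids <- sprintf("R%0*d", max(3, nchar(n)), seq_len(n))
  nF <- round(n * spec@sexRatio)
  sex <- sample(c(rep("female", nF), rep("male", n - nF)))
  st <- truth@sites
  A1 <- .draw_alleles(st$af, n)
  A2 <- .draw_alleles(st$af, n)
  male <- sex == "male"
  hap <- matrix(FALSE, n, nrow(st))
  hap[, st$category == "mito"] <- TRUE
  hap[male, st$category == "chrX" & !st$maleDiploid] <- TRUE
  A2[hap] <- NA_integer_
  new("CohortTruth", spec = spec,
      samples = data.frame(id = ids, sex = sex, role = "founder",
                           relatedTo = NA_character_,
                           stringsAsFactors = FALSE),
      sites = st, A1 = A1, A2 = A2,
      yDepthRatio = ifelse(male, 0.5, 0), autoDepth = rep(spec@depthMean, n))
}

#' Mitochondrial records on both linearizations
#'
#' Derives the two per-linearization record sets the circular-genome caller
#' consumes. The same observed genotypes feed both (the underlying reads are
#' the same); each linearization then loses the calls within `edgeDropout`
#' bases of its own breakpoint ends, emulating the edge effects the shifted
#' linearization exists to repair.
#'
#' @param truth a [CohortTruth] whose plan includes a mito contig.
#' @param shift breakpoint shift (default 10,000).
#' @param edgeDropout bases lost at each linearization end (default 100).
#' @param bqsrLike see [cohortRecords()].
#' @return list of record tables `primary` and `shifted` (the latter in
#'   shifted coordinates).
#' @export
mtLinearizedRecords <- function(truth, shift = 10000, edgeDropout = 100,
                                bqsrLike = FALSE) {
  mt <- truth@spec@contigPlan$name[truth@spec@contigPlan$category == "mito"]
  if (length(mt) != 1) stop("truth must contain exactly one mito contig")
  L <- truth@spec@contigPlan$length[truth@spec@contigPlan$category == "mito"]
  recs <- cohortRecords(truth, bqsrLike = bqsrLike)
  allmt <- data.table::rbindlist(recs)[contig == mt]
  prim <- allmt[pos > edgeDropout & pos <= L - edgeDropout]
  shif <- data.table::copy(allmt)
  shif$pos <- as.integer(mtUnmap(shif$pos, L, shift))
  shif <- shif[pos > edgeDropout & pos <= L - edgeDropout]
  data.table::setorder(shif, sample, pos)
  list(primary = prim, shifted = shif, L = L, shift = shift)
}

#' Simulate a two-population structured genotype matrix
#'
#' Ancestral allele frequencies are drawn from the cohort Beta prior
#' (conditioned to be common) and each population's frequencies from the
#' Balding-Nichols model at divergence `fst`; genotypes are Hardy-Weinberg
#' draws within populations. Used to exercise the PCA workflow's ability to
#' separate diverged subpopulations.
#'
#' @param nPerPop samples per population (two populations).
#' @param nVariants variant count.
#' @param fst divergence parameter.
#' @param seed RNG seed.
#' @param missingRate per-entry missing probability.
#' @return list: `gm` (a [GenotypeMatrix]) and `labels` (population id per
#'   sample).
#' @export
simulateStructuredMatrix <- function(nPerPop = 100, nVariants = 2000,
                                     fst = 0.1, seed = 1, missingRate = 0) {
  set.seed(seed)
  p0 <- stats::runif(nVariants, 0.1, 0.9)
  bn <- function(p) stats::rbeta(length(p), p * (1 - fst) / fst,
                                 (1 - p) * (1 - fst) / fst)
  pA <- bn(p0)
  pB <- bn(p0)
  n <- 2 * nPerPop
  draw <- function(p, n) matrix(stats::rbinom(n * length(p), 2,
                                              rep(p, each = n)), n,
                                length(p))
  d <- rbind(draw(pA, nPerPop), draw(pB, nPerPop))
  if (missingRate > 0)
    d[matrix(stats::runif(length(d)) < missingRate, nrow(d), ncol(d))] <- NA
  variants <- data.frame(contig = "1", pos = seq_len(nVariants) * 10L,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  labels <- rep(c("popA", "popB"), each = nPerPop)
  gm <- GenotypeMatrix(d, variants,
                       samples = sprintf("P%03d", seq_len(n)))
  list(gm = gm, labels = labels)
}
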