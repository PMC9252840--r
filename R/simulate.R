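# Synthetic consanguineous-pedigree VCF simulator.
#
# Emulates the data a mapping study starts from: a multi-sample VCF of
# biallelic SNVs with per-sample GT:DP, Hardy-Weinberg genotypes at
# polymorphic sites, and planted segments of the kinds the method must
# handle — an autozygous segment shared identical-by-descent by the
# affected siblings, homozygous-but-discordant segments (different
# haplotypes), hemizygous stretches (haploid calls) and homozygous
# deletions (no calls, zero depth) — plus InDels, no-calls and
# low-coverage genotypes as noise.  Sites are placed uniformly at random
# along each chromosome; linkage disequilibrium and exome target
# clustering are deliberately not modelled.

#' Build a simulation specification
#'
#' Defaults describe a consanguineous quartet study: two affected sibs and
#' their two parents, 20,000 polymorphic SNVs on two chromosomes, one
#' planted 500-marker autozygous segment shared by the sibs, 2\%
#' no-call / low-coverage / InDel rates and no genotype errors.  Allele
#' frequencies are drawn from Uniform(0.05, 0.5) so sites are informative
#' for run detection.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param nSites integer vector of SNV counts per chromosome (recycled).
#' @param samples character vector of sample names.
#' @param roles character vector: \code{"patient"} or \code{"control"} per
#'   sample.
#' @param segments data.frame of planted segments with columns
#'   \code{chrom}, \code{type} (one of \code{"autozygous_shared"},
#'   \code{"homozygous_discordant"}, \code{"hemizygous"},
#'   \code{"homozygous_deletion"}), \code{carriers} (comma-separated
#'   sample names) and either \code{start}/\code{end} in bp or
#'   \code{startMarker}/\code{nMarkers} in marker units; \code{NULL} for
#'   none.
#' @param afRange allele-frequency range for Uniform sampling.
#' @param indelRate fraction of sites converted to InDels.
#' @param nocallRate per-call probability of a missing genotype.
#' @param lowDpRate per-call probability of a low-coverage depth (DP drawn
#'   from 0..5).
#' @param genotypeErrorRate per-call probability of a HOM/HET flip.
#' @param dpMean mean sequencing depth for ordinary calls (Poisson).
#' @param seed RNG seed; the output VCF is byte-identical for equal seeds.
#' @return a list of class \code{"azSimSpec"}.
#' @export
simSpec <- function(chromLengths = c(chr1 = 120e6, chr2 = 120e6),
                    nSites = 10000L,
                    samples = c("Patient1", "Patient2", "Father", "Mother"),
                    roles = c("patient", "patient", "control", "control"),
                    segments = data.frame(chrom = "chr1",
                      type = "autozygous_shared", startMarker = 4000L,
                      nMarkers = 500L,
                      carriers = "Patient1,Patient2",
                      stringsAsFactors = FALSE),
                    afRange = c(0.05, 0.5), indelRate = 0.02,
                    nocallRate = 0.02, lowDpRate = 0.02,
                    genotypeErrorRate = 0, dpMean = 30, seed = 1L) {
  nSites <- rep_len(as.integer(nSites), length(chromLengths))
  rates <- c(indelRate, nocallRate, lowDpRate, genotypeErrorRate)
  if (any(rates < 0 | rates > 1))
    .azStop("config", "all rates must lie in [0, 1]")
  if (length(roles) != length(samples))
    .azStop("config", "roles must match samples")
  if (!is.null(segments) && nrow(segments)) {
    if (!all(segments$chrom %in% names(chromLengths)))
      .azStop("config", "planted segment on unknown chromosome")
    if (!all(segments$type %in% c("autozygous_shared",
        "homozygous_discordant", "hemizygous", "homozygous_deletion")))
      .azStop("config", "unknown planted segment type")
  }
  structure(list(chromLengths = chromLengths, nSites = nSites,
    samples = samples, roles = roles, segments = segments,
    afRange = afRange, indelRate = indelRate, nocallRate = nocallRate,
    lowDpRate = lowDpRate, genotypeErrorRate = genotypeErrorRate,
    dpMean = dpMean, seed = as.integer(seed)), class = "azSimSpec")
}

#' Simulate a multi-sample VCF with planted segments
#'
#' Outside planted segments, genotypes are drawn per sample independently
#' under Hardy-Weinberg equilibrium from each site's allele frequency.
#' Inside an \code{autozygous_shared} segment all carriers are homozygous
#' for one shared randomly drawn haplotype; in a
#' \code{homozygous_discordant} segment each carrier gets its own
#' haplotype; \code{hemizygous} segments yield haploid GT values;
#' \code{homozygous_deletion} segments yield missing genotypes with DP 0.
#' InDel, no-call, low-coverage and genotype-error noise are applied at
#' the specified rates.  Deterministic for a fixed seed (the seed is set
#' internally from \code{spec$seed}).
#'
#' @param spec an [simSpec()] object.
#' @param path output VCF path.
#' @param truthPath optional path for the planted-segment truth table
#'   (TSV).
#' @return a list: \code{vcf} (path), \code{truth} (data.frame of planted
#'   segments with their realised SNV-marker bounds and counts) and
#'   \code{states} (the simulator's own samples x SNV-sites genotype-state
#'   matrix, NOCALL where the genotype is missing — the ingest oracle at
#'   coverage threshold 0).
#' @export
simulateVcf <- function(spec, path, truthPath = NULL) {
  stopifnot(inherits(spec, "azSimSpec"))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  nsamp <- length(spec$samples)
  allChrom <- character(0); allPos <- numeric(0)
  allRef <- character(0); allAlt <- character(0)
  gtAll <- NULL; dpAll <- NULL; indelAll <- logical(0)
  truth <- NULL

  for (ci in seq_along(spec$chromLengths)) {
    ch <- names(spec$chromLengths)[ci]
    n <- spec$nSites[ci]
    len <- spec$chromLengths[ci]
    pos <- sort(sample.int(len, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    p <- stats::runif(n, spec$afRange[1], spec$afRange[2])

    # HWE genotype codes: 0 = 0/0, 1 = 0/1, 2 = 1/1
    u <- matrix(stats::runif(n * nsamp), nrow = nsamp, byrow = TRUE)
    pr0 <- matrix((1 - p)^2, nrow = nsamp, ncol = n, byrow = TRUE)
    pr1 <- matrix(2 * p * (1 - p), nrow = nsamp, ncol = n, byrow = TRUE)
    gt <- matrix("0/0", nrow = nsamp, ncol = n,
                 dimnames = list(spec$samples, NULL))
    gt[u >= pr0 & u < pr0 + pr1] <- "0/1"
    gt[u >= pr0 + pr1] <- "1/1"
    dp <- matrix(stats::rpois(n * nsamp, spec$dpMean), nrow = nsamp)

    segs <- spec$segments
    segs <- if (is.null(segs)) NULL else segs[segs$chrom == ch, , drop = FALSE]
    segTruth <- NULL
    if (!is.null(segs) && nrow(segs)) {
      for (si in seq_len(nrow(segs))) {
        sg <- segs[si, ]
        if (!is.null(sg$startMarker) && !is.na(sg$startMarker)) {
          mk <- sg$startMarker:(sg$startMarker + sg$nMarkers - 1L)
          if (max(mk) > n)
            .azStop("config", "planted segment exceeds site count on ", ch)
        } else {
          if (sg$end > len)
            .azStop("config", "planted segment outside chromosome bounds")
          mk <- which(pos >= sg$start & pos <= sg$end)
        }
        carriers <- strsplit(sg$carriers, ",", fixed = TRUE)[[1]]
        ci2 <- match(carriers, spec$samples)
        if (anyNA(ci2)) .azStop("config", "unknown carrier sample")
        pm <- p[mk]
        if (sg$type == "autozygous_shared") {
          hap <- stats::rbinom(length(mk), 1L, pm)
          for (k in ci2) gt[k, mk] <- paste0(hap, "/", hap)
        } else if (sg$type == "homozygous_discordant") {
          for (k in ci2) {
            hap <- stats::rbinom(length(mk), 1L, pm)
            gt[k, mk] <- paste0(hap, "/", hap)
          }
        } else if (sg$type == "hemizygous") {
          for (k in ci2) {
            hap <- stats::rbinom(length(mk), 1L, pm)
            gt[k, mk] <- as.character(hap)
          }
        } else if (sg$type == "homozygous_deletion") {
          for (k in ci2) {
            gt[k, mk] <- "./."
            dp[k, mk] <- 0L
          }
        }
        segTruth <- rbind(segTruth, data.frame(chrom = ch,
          type = sg$type, carriers = sg$carriers,
          firstMarker = min(mk), lastMarker = max(mk),
          stringsAsFactors = FALSE))
      }
    }

    # noise: genotype errors, then no-calls and low coverage
    delMask <- gt == "./."
    if (spec$genotypeErrorRate > 0) {
      err <- matrix(stats::runif(n * nsamp) < spec$genotypeErrorRate,
                    nrow = nsamp) & !delMask
      hom <- err & gt %in% c("0/0", "1/1")
      het <- err & gt == "0/1"
      gt[hom] <- "0/1"
      gt[het] <- sample(c("0/0", "1/1"), sum(het), replace = TRUE)
    }
    if (spec$nocallRate > 0) {
      nc <- matrix(stats::runif(n * nsamp) < spec$nocallRate,
                   nrow = nsamp) & !delMask
      gt[nc] <- "./."
    }
    if (spec$lowDpRate > 0) {
      lo <- matrix(stats::runif(n * nsamp) < spec$lowDpRate,
                   nrow = nsamp) & !delMask
      dp[lo] <- sample(0:5, sum(lo), replace = TRUE)
    }

    # convert a fraction of sites into InDels (insertions and deletions)
    isIndel <- logical(n)
    if (spec$indelRate > 0) {
      nIndel <- floor(spec$indelRate * n)
      if (nIndel > 0) {
        ii <- sort(sample.int(n, nIndel))
        ins <- seq_along(ii) %% 2L == 0L
        alt[ii[ins]] <- paste0(ref[ii[ins]],
          sample(bases, sum(ins), replace = TRUE))
        refDel <- ii[!ins]
        ref[refDel] <- paste0(ref[refDel],
          sample(bases, length(refDel), replace = TRUE))
        isIndel[ii] <- TRUE
      }
    }

    # realised truth bounds over SNV markers only
    if (!is.null(segTruth) && nrow(segTruth)) {
      for (si in seq_len(nrow(segTruth))) {
        mk <- segTruth$firstMarker[si]:segTruth$lastMarker[si]
        mk <- mk[!isIndel[mk]]
        segTruth$start[si] <- pos[min(mk)]
        segTruth$end[si] <- pos[max(mk)]
        segTruth$nMarkers[si] <- length(mk)
      }
      truth <- rbind(truth, segTruth)
    }

    allChrom <- c(allChrom, rep(ch, n)); allPos <- c(allPos, pos)
    allRef <- c(allRef, ref); allAlt <- c(allAlt, alt)
    gtAll <- cbind(gtAll, gt); dpAll <- cbind(dpAll, dp)
    indelAll <- c(indelAll, isIndel)
  }

  header <- c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(spec$chromLengths),
            as.integer(spec$chromLengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", spec$samples), collapse = "\t"))
  fields <- matrix(paste0(gtAll, ":", dpAll), nrow = nrow(gtAll))
  recs <- paste(allChrom, format(allPos, scientific = FALSE, trim = TRUE),
                ".", allRef, allAlt, ".", ".", ".", "GT:DP",
                sep = "\t")
  for (i in seq_len(nrow(fields)))
    recs <- paste(recs, fields[i, ], sep = "\t")
  writeLines(c(header, recs), path)

  snv <- !indelAll
  states <- matrix(.gtToState(gtAll[, snv, drop = FALSE],
                              allRef[snv], allAlt[snv]),
                   nrow = nsamp, dimnames = list(spec$samples, NULL))
  if (!is.null(truth)) {
    truth <- truth[, c("chrom", "start", "end", "type", "carriers",
                       "nMarkers")]
    if (!is.null(truthPath))
      utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  list(vcf = path, truth = truth, states = states)
}

# Simulator-side genotype-state bookkeeping (independent of the VCF path):
# maps its own GT codes to states, ignoring depth.
.gtToState <- function(gt, ref, alt) {
  n <- ncol(gt)
  out <- matrix("NOCALL", nrow = nrow(gt), ncol = n)
  refm <- matrix(ref, nrow = nrow(gt), ncol = n, byrow = TRUE)
  altm <- matrix(substr(alt, 1, 1), nrow = nrow(gt), ncol = n, byrow = TRUE)
  out[gt == "0/0" | gt == "0"] <- refm[gt == "0/0" | gt == "0"]
  out[gt == "1/1" | gt == "1"] <- altm[gt == "1/1" | gt == "1"]
  out[gt == "0/1"] <- "HET"
  out
}

#' Reciprocal overlap of detected regions with planted truth
#'
#' For each planted segment, the maximum over detected regions of
#' intersection/union in bp (1 for identical intervals, 0 for disjoint
#' ones).  Both sides use 1-based inclusive marker-bound coordinates.
#'
#' @param detected \code{GRanges} of detected regions.
#' @param truth data.frame as returned in \code{simulateVcf()$truth}.
#' @return numeric vector, one value per truth segment.
#' @export
truthOverlap <- function(detected, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    same <- as.character(seqnames(detected)) == truth$chrom[i]
    if (!any(same)) return(0)
    ds <- start(detected)[same]; de <- end(detected)[same]
    inter <- pmax(0, pmin(de, truth$end[i]) - pmax(ds, truth$start[i]) + 1)
    un <- (de - ds + 1) + (truth$end[i] - truth$start[i] + 1) - inter
    max(inter / un)
  }, numeric(1))
}
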