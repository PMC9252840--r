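# Run-of-homozygosity detection, shared-region intersection and
# autozygosity refinement.
#
# Runs and regions are represented as GRanges whose start/end are the
# positions of the first and last supporting markers (1-based, inclusive);
# metadata columns carry the marker-index bounds so callers can move
# between physical and marker coordinates.  A minimum of `minRun`
# consecutive run-compatible markers guards against spurious hits, e.g. a
# few homozygous genotypes flanking a long stretch not covered in the VCF.
#
# Internally everything works on plain integer index pairs; GRanges are
# only built at the user-facing surface.

.chromIndex <- function(gm) {
  chrom <- as.character(seqnames(gm@sites))
  split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
}

# Maximal TRUE-stretches of `flag` restricted to marker indices `idx`
# (one chromosome), as (start, end) global index pairs with length >= minRun.
.maximalStretches <- function(flag, idx, minRun) {
  r <- rle(flag[idx])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  cbind(start = unname(idx[starts[keep]]), end = unname(idx[ends[keep]]))
}

# Per-chromosome maximal stretches over the whole site axis.
.stretchesByChrom <- function(flag, chromIdx, minRun) {
  segs <- do.call(rbind, lapply(chromIdx, function(idx)
    .maximalStretches(flag, idx, minRun)))
  if (is.null(segs)) matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("start", "end")))
  else segs
}

# Index pairs of one sample's runs, from its decoded state row.
.runsIdx <- function(stateRow, chromIdx, minRun) {
  .stretchesByChrom(stateRow != "HET", chromIdx, minRun)
}

# Per-marker run membership for one sample.
.membership <- function(stateRow, chromIdx, minRun) {
  segs <- .runsIdx(stateRow, chromIdx, minRun)
  mem <- logical(length(stateRow))
  for (r in seq_len(nrow(segs)))
    mem[segs[r, 1L]:segs[r, 2L]] <- TRUE
  mem
}

.runGRanges <- function(gm, startIdx, endIdx, extra = list()) {
  pos <- start(gm@sites)
  chrom <- as.character(seqnames(gm@sites))
  startIdx <- as.integer(unname(startIdx))
  endIdx <- as.integer(unname(endIdx))
  gr <- GRanges(factor(chrom[startIdx], levels = unique(chrom)),
                IRanges(pos[startIdx], pos[endIdx]))
  mcols(gr)$startIdx <- startIdx
  mcols(gr)$endIdx <- endIdx
  mcols(gr)$nMarkers <- endIdx - startIdx + 1L
  for (nm in names(extra)) mcols(gr)[[nm]] <- unname(extra[[nm]])
  gr
}

#' Find a sample's runs of homozygosity
#'
#' Returns every maximal stretch of run-compatible markers (homozygous for
#' any base, or NOCALL) of at least \code{minRun} markers, per chromosome.
#' Runs are flanked by heterozygous markers or chromosome ends, never
#' overlap, and are reported sorted.  Runs consisting entirely of NOCALL
#' markers are retained: a long homozygous deletion yields exactly such a
#' run.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sample sample name.
#' @param minRun minimum run length in markers (default 15).
#' @return \code{GRanges} with metadata columns \code{sample},
#'   \code{startIdx}, \code{endIdx}, \code{nMarkers} and \code{nCalled}
#'   (markers with a real homozygous call, i.e. excluding NOCALL).
#' @export
findSampleRuns <- function(gm, sample, minRun = 15L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!sample %in% gm@samples)
    .azStop("config", "unknown sample: ", sample)
  st <- genotypes(gm)[sample, ]
  segs <- .runsIdx(st, .chromIndex(gm), minRun)
  if (nrow(segs) == 0L) return(.emptyRuns())
  hom <- st != "HET" & st != "NOCALL"
  csum <- cumsum(hom)
  nCalled <- csum[segs[, 2L]] - csum[segs[, 1L]] + hom[segs[, 1L]]
  .runGRanges(gm, segs[, 1L], segs[, 2L],
              list(sample = sample, nCalled = as.integer(nCalled)))
}

.emptyRuns <- function() {
  gr <- GRanges()
  mcols(gr) <- S4Vectors::DataFrame(startIdx = integer(0), endIdx = integer(0),
    nMarkers = integer(0), sample = character(0), nCalled = integer(0))
  gr
}

.emptyRegions <- function() {
  gr <- GRanges()
  mcols(gr) <- S4Vectors::DataFrame(startIdx = integer(0), endIdx = integer(0),
    nMarkers = integer(0), mode = character(0), patients = character(0),
    scoreMax = numeric(0))
  gr
}

#' Shared homozygous regions across patients
#'
#' Intersects the patients' runs of homozygosity: a shared region is a
#' maximal stretch of at least \code{minRun} markers at each of which at
#' least \code{minPatients} patients lie inside one of their own runs.
#' With a single patient this reduces exactly to [findSampleRuns()].  The
#' haplotype is not compared here — that is [autozygosityRefine()]'s job —
#' so regions found in this mode suit patients from different families,
#' where different haplotypes are likely.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param patients character vector of patient sample names.
#' @param minPatients integer or \code{"all"} (default): support required
#'   at every marker.
#' @param minRun minimum region length in markers (default 15).
#' @return \code{GRanges} with metadata columns \code{startIdx},
#'   \code{endIdx}, \code{nMarkers}, \code{mode} (\code{"homozygous"}),
#'   \code{patients} (comma-separated supporting patients, i.e. those whose
#'   runs overlap the region) and \code{scoreMax} (NA until scored).
#' @export
sharedRegions <- function(gm, patients, minPatients = "all", minRun = 15L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!length(patients)) .azStop("config", "patients must be non-empty")
  bad <- setdiff(patients, gm@samples)
  if (length(bad)) .azStop("config", "unknown sample: ",
                           paste(bad, collapse = ", "))
  k <- if (identical(minPatients, "all") || is.na(minPatients))
    length(patients) else as.integer(minPatients)
  if (k > length(patients))
    .azStop("config", "minPatients (", k, ") exceeds the number of patients (",
            length(patients), ")")
  states <- genotypes(gm)
  chromIdx <- .chromIndex(gm)
  ind <- matrix(FALSE, nrow = length(gm@sites), ncol = length(patients))
  for (j in seq_along(patients))
    ind[, j] <- .membership(states[patients[j], ], chromIdx, minRun)
  support <- rowSums(ind)
  segs <- .stretchesByChrom(support >= k, chromIdx, minRun)
  if (nrow(segs) == 0L) return(.emptyRegions())
  supp <- vapply(seq_len(nrow(segs)), function(r) {
    rows <- segs[r, 1L]:segs[r, 2L]
    paste(patients[colSums(ind[rows, , drop = FALSE]) > 0L], collapse = ",")
  }, character(1))
  .runGRanges(gm, segs[, 1L], segs[, 2L],
              list(mode = "homozygous", patients = supp,
                   scoreMax = NA_real_))
}

#' Refine shared homozygous regions into autozygous segments
#'
#' Within each shared region, tests at every site whether the supporting
#' patients are homozygous for the same base ([isAlleleConcordant()];
#' NOCALL acts as a wildcard).  The region is split at every discordant
#' site — the discordant marker itself belongs to neither sub-segment, it
#' marks the end of the autozygous part — and maximal concordant
#' sub-segments of at least \code{minRun} markers are returned with
#' \code{mode = "autozygous"}.  Patients homozygous for the same haplotype
#' across a segment are consistent with having inherited it identical by
#' descent, which is the expectation within a consanguineous family.
#'
#' @param regions \code{GRanges} from [sharedRegions()] (mode
#'   \code{"homozygous"}).
#' @param gm the [GenotypeMatrix-class] the regions were computed from.
#' @param patients patient names; defaults to each region's supporting
#'   patients.
#' @param minRun minimum segment length in markers (default 15).
#' @return \code{GRanges} of autozygous segments, same metadata layout as
#'   [sharedRegions()]; the union of the output is contained in the input.
#' @export
autozygosityRefine <- function(regions, gm, patients = NULL, minRun = 15L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!length(regions)) return(.emptyRegions())
  if (!all(mcols(regions)$mode == "homozygous"))
    .azStop("config", "autozygosityRefine() expects homozygous-mode regions")
  states <- genotypes(gm)
  chromIdx <- .chromIndex(gm)
  memCache <- new.env(parent = emptyenv())
  getMem <- function(p) {
    if (is.null(memCache[[p]]))
      memCache[[p]] <- .membership(states[p, ], chromIdx, minRun)
    memCache[[p]]
  }
  allStart <- integer(0); allEnd <- integer(0); allPat <- character(0)
  for (r in seq_along(regions)) {
    pts <- if (is.null(patients))
      strsplit(mcols(regions)$patients[r], ",", fixed = TRUE)[[1]]
    else patients
    idx <- mcols(regions)$startIdx[r]:mcols(regions)$endIdx[r]
    sub <- states[pts, idx, drop = FALSE]
    inRun <- do.call(rbind, lapply(pts, function(p) getMem(p)[idx]))
    # a site is concordant iff, among patients inside their own run there,
    # at most one distinct homozygous base occurs (NOCALL = wildcard)
    nBases <- Reduce(`+`, lapply(.HOM_STATES, function(b)
      as.integer(colSums(sub == b & inRun) > 0L)))
    segs <- .maximalStretches(nBases <= 1L, seq_along(idx), minRun)
    if (nrow(segs)) {
      allStart <- c(allStart, idx[segs[, 1L]])
      allEnd <- c(allEnd, idx[segs[, 2L]])
      allPat <- c(allPat, rep(mcols(regions)$patients[r], nrow(segs)))
    }
  }
  if (!length(allStart)) return(.emptyRegions())
  .runGRanges(gm, allStart, allEnd,
              list(mode = "autozygous", patients = allPat,
                   scoreMax = NA_real_))
}

#' Rank regions by physical length
#'
#' Regions are ordered by their real length in base pairs (descending)
#' rather than by marker count: a region spanning few markers can still be
#' physically long.  Ties break by marker count (descending), then by
#' chromosome and start position (ascending).
#'
#' @param regions \code{GRanges} of shared/autozygous regions.
#' @return the same \code{GRanges}, reordered, with a \code{rank} metadata
#'   column added (1 = longest).
#' @export
rankRegions <- function(regions) {
  if (!length(regions)) {
    mcols(regions)$rank <- integer(0)
    return(regions)
  }
  o <- order(-width(regions), -mcols(regions)$nMarkers,
             as.integer(seqnames(regions)), start(regions))
  regions <- regions[o]
  mcols(regions)$rank <- seq_along(regions)
  regions
}
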