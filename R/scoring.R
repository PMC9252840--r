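# Genome-wide homozygosity score.
#
# The per-marker raw score sums, over patients, the length (in markers) of
# the run of homozygosity enclosing the marker, minus a weighted control
# sum, floored at zero.  Long runs shared by several patients therefore
# tower over short private runs, and controls sharing the same run pull a
# region down.  The relative score divides by the single genome-wide
# maximum, so the display has one natural 100% peak.

#' Per-marker enclosing-run length for one sample
#'
#' L(m) is the marker count of the sample's run of homozygosity containing
#' marker m, or 0 when m lies in no run.  This is the quantity that drives
#' both the score and the colour intensity of the genotype grid.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param sample sample name.
#' @param minRun minimum run length in markers (default 15).
#' @return integer vector, one entry per site of \code{gm}.
#' @export
runLengthTrack <- function(gm, sample, minRun = 15L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!sample %in% gm@samples)
    .azStop("config", "unknown sample: ", sample)
  .runLengths(genotypes(gm)[sample, ], .chromIndex(gm), minRun)
}

.runLengths <- function(stateRow, chromIdx, minRun) {
  segs <- .runsIdx(stateRow, chromIdx, minRun)
  L <- integer(length(stateRow))
  for (k in seq_len(nrow(segs)))
    L[segs[k, 1L]:segs[k, 2L]] <- segs[k, 2L] - segs[k, 1L] + 1L
  L
}

#' Compute the genome-wide homozygosity score track
#'
#' S(m) = max(0, sum over patients of L_p(m) - controlWeight * sum over
#' controls of L_c(m)), where L is [runLengthTrack()].  With no controls S
#' is the plain patient sum.  The relative score R = S / max(S) is
#' normalised over the whole genome (not per chromosome); when no run
#' exists anywhere, R is identically zero.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param patients character vector of patient names (non-empty).
#' @param controls character vector of control names (may be empty;
#'   controls are optional throughout).
#' @param controlWeight non-negative weight for the control sum (default 1).
#' @param minRun minimum run length in markers (default 15).
#' @return a [ScoreTrack-class].
#' @export
scoreTrack <- function(gm, patients, controls = character(),
                       controlWeight = 1, minRun = 15L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!length(patients)) .azStop("config", "patients must be non-empty")
  bad <- setdiff(c(patients, controls), gm@samples)
  if (length(bad)) .azStop("config", "unknown sample: ",
                           paste(bad, collapse = ", "))
  n <- length(gm@sites)
  states <- genotypes(gm)
  chromIdx <- .chromIndex(gm)
  S <- numeric(n)
  for (p in patients) S <- S + .runLengths(states[p, ], chromIdx, minRun)
  if (length(controls) && controlWeight > 0) {
    C <- numeric(n)
    for (ct in controls) C <- C + .runLengths(states[ct, ], chromIdx, minRun)
    S <- pmax(0, S - controlWeight * C)
  }
  mx <- if (n) max(S) else 0
  R <- if (mx > 0) S / mx else numeric(n)
  new("ScoreTrack", sites = gm@sites, score = S, relScore = R)
}

#' Candidate regions above a relative-score threshold
#'
#' Returns the maximal marker intervals whose relative score is strictly
#' greater than \code{scoreFraction} and which span at least \code{minRun}
#' markers — the intervals highlighted in the genome-wide score plot
#' (default: higher than 60\% of the maximum).
#'
#' @param track a [ScoreTrack-class].
#' @param scoreFraction threshold in (0, 1] (default 0.6); the comparison
#'   is strict, so \code{scoreFraction = 1} yields no candidates.
#' @param minRun minimum interval length in markers (default 15).
#' @return \code{GRanges} with \code{startIdx}, \code{endIdx},
#'   \code{nMarkers} and \code{scoreMax} (maximum relative score inside),
#'   sorted by position; empty for an all-zero track.
#' @export
candidateRegions <- function(track, scoreFraction = 0.6, minRun = 15L) {
  stopifnot(is(track, "ScoreTrack"))
  if (!(scoreFraction > 0 && scoreFraction <= 1))
    .azStop("config", "scoreFraction must be in (0, 1]")
  above <- track@relScore > scoreFraction
  chrom <- as.character(seqnames(track@sites))
  idxByChrom <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
  segs <- .stretchesByChrom(above, idxByChrom, minRun)
  if (nrow(segs) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(startIdx = integer(0),
      endIdx = integer(0), nMarkers = integer(0), scoreMax = numeric(0))
    return(gr)
  }
  pos <- start(track@sites)
  s <- as.integer(segs[, "start"]); e <- as.integer(segs[, "end"])
  gr <- GRanges(factor(chrom[s], levels = unique(chrom)),
                IRanges(pos[s], pos[e]))
  mcols(gr)$startIdx <- s
  mcols(gr)$endIdx <- e
  mcols(gr)$nMarkers <- e - s + 1L
  mcols(gr)$scoreMax <- vapply(seq_len(nrow(segs)), function(r)
    max(track@relScore[s[r]:e[r]]), numeric(1))
  sort(gr, ignore.strand = TRUE)
}

#' Annotate regions with their maximum relative score
#'
#' Fills the \code{scoreMax} metadata column of shared/autozygous regions
#' from a score track computed on the same genotype matrix.
#'
#' @param regions \code{GRanges} from [sharedRegions()] or
#'   [autozygosityRefine()].
#' @param track a [ScoreTrack-class] over the same sites.
#' @return the regions with \code{scoreMax} set.
#' @export
annotateRegionScores <- function(regions, track) {
  stopifnot(is(track, "ScoreTrack"))
  if (!length(regions)) return(regions)
  mcols(regions)$scoreMax <- vapply(seq_along(regions), function(r)
    max(track@relScore[mcols(regions)$startIdx[r]:mcols(regions)$endIdx[r]]),
    numeric(1))
  regions
}

#' Write a score track as bedGraph
#'
#' Emits (chrom, 0-based start, end, score) lines; stretches of contiguous
#' markers with equal score are merged into one interval spanning from the
#' first to the last marker of the stretch.
#'
#' @param track a [ScoreTrack-class].
#' @param path output file.
#' @param what \code{"relative"} (default) or \code{"raw"}.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(track, path, what = c("relative", "raw")) {
  what <- match.arg(what)
  val <- if (what == "relative") track@relScore else track@score
  chrom <- as.character(seqnames(track@sites))
  pos <- start(track@sites)
  lines <- character(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    r <- rle(val[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lines <- c(lines, sprintf("%s\t%d\t%d\t%g", ch,
      pos[idx[starts]] - 1L, pos[idx[ends]], r$values))
  }
  writeLines(lines, path)
  invisible(path)
}
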