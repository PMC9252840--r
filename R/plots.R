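# Static plots: genome-wide score overview and per-region genotype grid.
# Devices are chosen from the file extension (.png, .svg, .pdf).

.openDevice <- function(path, width = 10, height = 6) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(path, width = width, height = height),
    pdf = grDevices::pdf(path, width = width, height = height),
    .azStop("config", "unsupported image format: .", ext,
            " (use .png, .svg or .pdf)"))
}

#' Genome-wide homozygosity score plot
#'
#' One panel per chromosome; bar height is the relative score, and markers
#' whose relative score exceeds \code{scoreFraction} (strictly) are drawn
#' in the highlight colour — by default, segments scoring higher than 60\%
#' of the genome-wide maximum.
#'
#' @param track a [ScoreTrack-class].
#' @param scoreFraction highlight threshold (default 0.6).
#' @param path output image (.png, .svg or .pdf).
#' @param highlightCol,baseCol colours for markers above/below the
#'   threshold.
#' @return invisibly, the integer indices of the highlighted markers (the
#'   same marker set as [candidateRegions()] covers, before the minimum-run
#'   filter is applied there).
#' @export
plotGenomeScores <- function(track, scoreFraction = 0.6, path,
                             highlightCol = "red2", baseCol = "grey40") {
  stopifnot(is(track, "ScoreTrack"))
  chrom <- as.character(seqnames(track@sites))
  chroms <- unique(chrom)
  pos <- start(track@sites)
  hi <- which(track@relScore > scoreFraction)
  .openDevice(path, width = 10, height = 1.8 * length(chroms) + 1)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(length(chroms), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (ch in chroms) {
    idx <- which(chrom == ch)
    cols <- ifelse(track@relScore[idx] > scoreFraction, highlightCol, baseCol)
    graphics::plot(NA, xlim = range(pos[idx]), ylim = c(0, 1),
                   xlab = "", ylab = "relative score", main = ch,
                   cex.main = 0.9)
    graphics::segments(pos[idx], 0, pos[idx], track@relScore[idx],
                       col = cols)
    graphics::abline(h = scoreFraction, lty = 3, col = "grey60")
  }
  invisible(hi)
}

.homIntensity <- function(runLength, maxLen) {
  # colour intensity strictly monotone in the enclosing-run length
  f <- ifelse(runLength <= 0, 0.15, 0.35 + 0.65 * runLength / max(maxLen, 1))
  grDevices::rgb(1, 1 - 0.85 * f, 1 - 0.85 * f)
}

#' Plot a per-region genotype grid
#'
#' Rows are patients (top) then controls; columns are SNV markers.
#' Homozygous genotypes are red squares whose intensity grows with the
#' length of the sample's run of homozygosity, heterozygous genotypes are
#' blue, no-calls grey.  Homozygous genotypes with different alleles
#' across the patients carry a diagonal bar — they mark the end of the
#' autozygous part of a shared homozygous region.  An optional box is
#' drawn around the patients' segment.
#'
#' @param grid a [GenotypeGrid-class] from [regionQuery()].
#' @param regionBox optional \code{GRanges} of length 1; its span is boxed
#'   across the patient rows.
#' @param path output image (.png, .svg or .pdf).
#' @return invisibly, a list with the colour matrix and the discordant
#'   column indices (for pixel-independent checks).
#' @export
plotRegionGrid <- function(grid, regionBox = NULL, path) {
  stopifnot(is(grid, "GenotypeGrid"))
  ns <- nrow(grid@states); nm <- ncol(grid@states)
  maxLen <- max(grid@runLength, 1L)
  cols <- matrix("grey75", ns, nm)
  hom <- grid@states %in% .HOM_STATES
  cols[grid@states == "HET"] <- "royalblue3"
  cols[hom] <- .homIntensity(grid@runLength[hom], maxLen)
  discCols <- which(grid@discordantSites)

  .openDevice(path, width = max(6, nm * 0.12), height = 1 + ns * 0.5)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(3, 6, 1, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::plot(NA, xlim = c(0, nm), ylim = c(0, ns), xaxs = "i",
                 yaxs = "i", axes = FALSE, xlab = "marker", ylab = "")
  for (i in seq_len(ns)) {
    y0 <- ns - i; y1 <- ns - i + 1
    graphics::rect(seq_len(nm) - 1, y0, seq_len(nm), y1,
                   col = cols[i, ], border = NA)
    disc <- which(grid@discordantSites &
                    grid@states[i, ] %in% .HOM_STATES)
    if (length(disc))
      graphics::segments(disc - 1, y0, disc, y1, col = "black", lwd = 1.5)
  }
  graphics::axis(2, at = ns - seq_len(ns) + 0.5,
                 labels = rownames(grid@states), las = 2, tick = FALSE,
                 cex.axis = 0.8)
  if (!is.null(regionBox) && length(regionBox)) {
    inBox <- which(start(grid@sites) >= start(regionBox)[1] &
                     start(grid@sites) <= end(regionBox)[1])
    if (length(inBox))
      graphics::rect(min(inBox) - 1, ns - length(grid@patients), max(inBox),
                     ns, border = "black", lwd = 2)
  }
  invisible(list(colors = cols, discordantColumns = discCols))
}
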