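# Export of detected regions (BED) and of the variants they contain (VCF),
# plus coordinate/gene queries into the genotype grid.

#' Write regions as a BED file
#'
#' One line per region with the standard 0-based half-open convention: a
#' region spanning 1-based positions \code{start..end} becomes
#' \code{chrom  start-1  end}.  The name column is \code{mode:rank} (rank
#' from [rankRegions()], by physical length) and the score column is
#' \code{round(1000 * scoreMax)} (0 where unscored).  Lines are sorted by
#' chromosome then start, ready for IGV or bedtools.
#'
#' @param regions \code{GRanges} of regions.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBed <- function(regions, path) {
  if (!length(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ranked <- rankRegions(regions)
  o <- order(as.character(seqnames(ranked)), start(ranked))
  ranked <- ranked[o]
  sc <- mcols(ranked)$scoreMax
  sc[is.na(sc)] <- 0
  lines <- sprintf("%s\t%d\t%d\t%s:%d\t%d",
    as.character(seqnames(ranked)), start(ranked) - 1L, end(ranked),
    mcols(ranked)$mode, mcols(ranked)$rank, as.integer(round(1000 * sc)))
  writeLines(lines, path)
  invisible(path)
}

#' Export the variants inside regions as a VCF
#'
#' Copies from the ingested VCF exactly those records whose POS falls
#' within a selected region on the same chromosome (1-based inclusive
#' bounds).  The record set is restricted by position only, so the export
#' contains \emph{all} variants inside the regions: InDels, which never
#' took part in the mapping, and sites where different patients are
#' homozygous for different alleles.  The input header is preserved
#' verbatim, with one provenance line added.  This positional restriction
#' is what shrinks a WES/WGS variant list to the positional candidates for
#' downstream disease-mutation tools.
#'
#' @param inputVcf path of the VCF that was ingested (plain or gzipped).
#' @param regions \code{GRanges} of selected regions.
#' @param path output VCF path.
#' @param topN if not \code{NULL}, restrict to the top-N regions by
#'   physical length ([rankRegions()]) before filtering.
#' @return number of exported records, invisibly.
#' @export
writeRegionVcf <- function(inputVcf, regions, path, topN = NULL) {
  con <- gzfile(inputVcf, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- startsWith(lines, "#")
  header <- lines[hdr]
  body <- lines[!hdr]

  if (!is.null(topN) && length(regions))
    regions <- utils::head(rankRegions(regions), topN)
  mode <- if (length(regions)) mcols(regions)$mode[1] else "none"
  prov <- sprintf("##autozygR_regions=%d,mode=%s", length(regions), mode)
  chromLine <- grep("^#CHROM", header)
  header <- append(header, prov,
                   after = if (length(chromLine)) chromLine[1] - 1L
                           else length(header))

  keep <- logical(length(body))
  if (length(body) && length(regions)) {
    chrom <- sub("\t.*$", "", body)
    pos <- as.numeric(sub("^[^\t]*\t([^\t]*)\t.*$", "\\1", body))
    absent <- setdiff(as.character(unique(seqnames(regions))), unique(chrom))
    if (length(absent))
      warning("region chromosome(s) absent from VCF: ",
              paste(absent, collapse = ", "))
    q <- GRanges(chrom, IRanges(pos, pos))
    keep <- IRanges::overlapsAny(q, regions, ignore.strand = TRUE)
  }
  writeLines(c(header, body[keep]), path)
  invisible(sum(keep))
}

.parseRegionString <- function(query) {
  m <- regmatches(query, regexec("^([^:]+):([0-9]+)-([0-9]+)$", query))[[1]]
  if (length(m) != 4L) return(NULL)
  GRanges(m[2], IRanges(as.numeric(m[3]), as.numeric(m[4])))
}

#' Genotype grid for a genomic region or gene
#'
#' Returns the genotype grid (states, enclosing-run lengths, discordance
#' flags) for every SNV marker inside the query span, regardless of any
#' run of homozygosity — for inspecting a candidate locus directly.
#' Coordinate queries are \code{"chrom:start-end"} (1-based inclusive);
#' gene-symbol queries need a user-supplied annotation BED of gene spans
#' whose name column carries the symbols (no gene models are built in).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param query \code{"chrom:start-end"} or a gene symbol.
#' @param annotation optional path to a BED file of gene spans (required
#'   for gene queries).
#' @param patients,controls sample names by role; default: all samples as
#'   patients.
#' @param minRun minimum run length for the run-length layer (default 15).
#' @return a [GenotypeGrid-class]; a span containing no marker yields an
#'   empty grid, not an error.
#' @export
regionQuery <- function(gm, query, annotation = NULL,
                        patients = sampleNames(gm), controls = character(),
                        minRun = 15L) {
  stopifnot(is(gm, "GenotypeMatrix"))
  span <- .parseRegionString(query)
  if (is.null(span)) {
    if (is.null(annotation))
      .azStop("config", "'", query, "' is not a coordinate query; ",
              "gene-symbol queries require an annotation BED ",
              "(chrom, start, end, gene name)")
    genes <- .readBedAnnotation(annotation)
    hit <- which(genes$name == query)
    if (!length(hit))
      .azStop("data", "gene symbol not found in annotation: ", query)
    span <- genes[hit[1]]
  }
  sel <- which(as.character(seqnames(gm@sites)) ==
                 as.character(seqnames(span))[1] &
               start(gm@sites) >= start(span)[1] &
               start(gm@sites) <= end(span)[1])
  ordered <- c(patients, controls)
  states <- genotypes(gm)[ordered, sel, drop = FALSE]
  rl <- t(matrix(unlist(lapply(ordered, function(s)
    runLengthTrack(gm, s, minRun)[sel])), ncol = length(ordered)))
  rownames(rl) <- ordered
  disc <- .discordantSites(states[patients, , drop = FALSE])
  new("GenotypeGrid", states = states,
      runLength = matrix(as.integer(rl), nrow = length(ordered),
                         dimnames = dimnames(rl)),
      discordantSites = disc, sites = gm@sites[sel],
      patients = patients, controls = controls)
}

# TRUE per column where >1 distinct homozygous base occurs among patients.
.discordantSites <- function(states) {
  if (!ncol(states)) return(logical(0))
  nBases <- Reduce(`+`, lapply(.HOM_STATES, function(b)
    as.integer(colSums(states == b, na.rm = TRUE) > 0L)))
  nBases > 1L
}

# Minimal BED reader for gene-span annotation (chrom, start0, end, name).
.readBedAnnotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    .azStop("data", "annotation BED needs at least 4 columns ",
            "(chrom, start, end, name): ", path)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  mcols(gr)$name <- df[[4]]
  gr
}
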