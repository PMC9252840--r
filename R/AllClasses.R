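#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- Rle
NULL

#' Bit-coded genotype matrix for SNV sites
#'
#' Stores one genotype state per (sample, SNV site) in a compact bit-coded
#' vector: the six states (four real-allele homozygous states, heterozygous,
#' no-call) are packed three genotypes per byte.  InDels never enter this
#' container; they are kept aside at ingest and only resurface when variants
#' are exported.
#'
#' @slot packed raw vector holding the base-6 packed genotype codes,
#'   sample-major within site (sample index varies fastest).
#' @slot samples character vector of sample names (rows).
#' @slot sites \code{GRanges} of SNV sites (columns), sorted by chromosome
#'   (order of first appearance) then position, with metadata columns
#'   \code{ref} and \code{alt} (comma-separated alternate alleles).
#'
#' @seealso [GenotypeMatrix()] for construction, [genotypes()],
#'   [findSampleRuns()], [sharedRegions()]
#' @export
setClass("GenotypeMatrix",
  representation(packed = "raw", samples = "character", sites = "GRanges"))

setValidity("GenotypeMatrix", function(object) {
  n <- length(object@samples) * length(object@sites)
  msg <- character()
  if (length(object@packed) != ceiling(n / 3))
    msg <- c(msg, "packed length inconsistent with samples x sites")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "duplicate sample names")
  s <- object@sites
  if (length(s)) {
    if (is.null(s$ref) || is.null(s$alt))
      msg <- c(msg, "sites must carry 'ref' and 'alt' metadata columns")
    else {
      alts <- strsplit(s$alt, ",", fixed = TRUE)
      if (any(nchar(s$ref) != 1L) || any(!vapply(alts, function(a)
            all(nchar(a) == 1L & !grepl("[<>]", a)), logical(1))))
        msg <- c(msg, "GenotypeMatrix must not contain InDel or symbolic sites")
      key <- paste(as.character(seqnames(s)), start(s), s$ref, s$alt)
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (chrom, pos, ref, alt) site")
      bychr <- split(start(s), as.character(seqnames(s)))
      if (any(vapply(bychr, is.unsorted, logical(1), strictly = TRUE)))
        msg <- c(msg, "site positions must be strictly increasing within chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' Bundles the tunable parameters of a homozygosity/autozygosity analysis.
#'
#' @slot minRun minimum number of consecutive run-compatible markers for a
#'   stretch to count as a run of homozygosity (default 15).
#' @slot coverageThreshold per-sample DP below which a genotype is treated
#'   as a no-call wildcard; 0 disables the rule (default 0).
#' @slot scoreFraction fraction of the genome-wide maximum score above which
#'   markers are flagged as candidate regions (default 0.6).
#' @slot controlWeight non-negative weight applied to control samples'
#'   run lengths when scoring (default 1).
#' @slot minPatients minimum number of patients that must be inside a run at
#'   each marker of a shared region; \code{NA} means all patients.
#' @slot mode \code{"homozygous"} or \code{"autozygous"}.
#'
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(minRun = "integer", coverageThreshold = "integer",
    scoreFraction = "numeric", controlWeight = "numeric",
    minPatients = "integer", mode = "character"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@minRun < 1L) msg <- c(msg, "minRun must be >= 1")
  if (object@coverageThreshold < 0L) msg <- c(msg, "coverageThreshold must be >= 0")
  if (!(object@scoreFraction > 0 && object@scoreFraction <= 1))
    msg <- c(msg, "scoreFraction must be in (0, 1]")
  if (object@controlWeight < 0) msg <- c(msg, "controlWeight must be >= 0")
  if (!is.na(object@minPatients) && object@minPatients < 1L)
    msg <- c(msg, "minPatients must be >= 1 or 'all'")
  if (!object@mode %in% c("homozygous", "autozygous"))
    msg <- c(msg, "mode must be 'homozygous' or 'autozygous'")
  if (length(msg)) msg else TRUE
})

#' Sample manifest: patients and optional controls
#'
#' Names the affected individuals whose shared homozygosity is mapped and,
#' optionally, unaffected relatives or other controls whose runs penalise
#' the score.  Controls are never required: runs of homozygosity are
#' determined from the patients alone.
#'
#' @slot patients character vector of affected sample names (at least one).
#' @slot controls character vector of control sample names (may be empty).
#'
#' @seealso [sampleManifest()], [validateManifest()]
#' @export
setClass("SampleManifest",
  representation(patients = "character", controls = "character"))

setValidity("SampleManifest", function(object) {
  msg <- character()
  if (length(object@patients) < 1L) msg <- c(msg, "need at least one patient")
  if (length(intersect(object@patients, object@controls)))
    msg <- c(msg, "patients and controls must be disjoint")
  if (anyDuplicated(object@patients) || anyDuplicated(object@controls))
    msg <- c(msg, "duplicate sample names in manifest")
  if (length(msg)) msg else TRUE
})

#' Genome-wide per-marker homozygosity score track
#'
#' Raw score S(m) at marker m is the sum of the patients' enclosing-run
#' lengths minus the weighted control sum, floored at zero; the relative
#' score R(m) divides by the genome-wide maximum, so max(R) == 1 whenever
#' any patient run exists.
#'
#' @slot sites \code{GRanges} of the marker positions (mirrors the
#'   \code{GenotypeMatrix} the track was computed from).
#' @slot score numeric raw score per marker, in marker units.
#' @slot relScore numeric relative score per marker in [0, 1]; identically
#'   zero when no run exists.
#'
#' @seealso [scoreTrack()], [candidateRegions()], [plotGenomeScores()]
#' @export
setClass("ScoreTrack",
  representation(sites = "GRanges", score = "numeric", relScore = "numeric"))

setValidity("ScoreTrack", function(object) {
  msg <- character()
  if (length(object@score) != length(object@sites) ||
      length(object@relScore) != length(object@sites))
    msg <- c(msg, "score/relScore length must match sites")
  if (length(object@score) && min(object@score) < 0)
    msg <- c(msg, "raw scores must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Genotype grid for a genomic region
#'
#' The per-sample, per-marker view rendered in region displays: genotype
#' state, the length of the sample's enclosing run of homozygosity (0 if
#' none), and whether the site breaks allele concordance across patients
#' (homozygous genotypes with different alleles).
#'
#' @slot states character matrix, samples x markers, of genotype states.
#' @slot runLength integer matrix of enclosing-run lengths, same shape.
#' @slot discordantSites logical per marker: TRUE where patients carry
#'   homozygous genotypes for different alleles.
#' @slot sites \code{GRanges} of the markers shown.
#' @slot patients,controls character vectors of row names by role.
#'
#' @seealso [regionQuery()], [plotRegionGrid()]
#' @export
setClass("GenotypeGrid",
  representation(states = "matrix", runLength = "matrix",
    discordantSites = "logical", sites = "GRanges",
    patients = "character", controls = "character"))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@samples), "samples x",
      length(object@sites), "SNV sites on",
      length(unique(as.character(seqnames(object@sites)))), "chromosome(s)\n")
  cat("  samples:", paste(utils::head(object@samples, 6), collapse = ", "),
      if (length(object@samples) > 6) "..." else "", "\n")
  cat("  packed store:", length(object@packed), "bytes\n")
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig: mode =", object@mode,
      "| minRun =", object@minRun,
      "| coverageThreshold =", object@coverageThreshold,
      "| scoreFraction =", object@scoreFraction,
      "| controlWeight =", object@controlWeight,
      "| minPatients =", if (is.na(object@minPatients)) "all"
        else object@minPatients, "\n")
})

setMethod("show", "SampleManifest", function(object) {
  cat("SampleManifest:", length(object@patients), "patient(s) [",
      paste(object@patients, collapse = ", "), "],",
      length(object@controls), "control(s)",
      if (length(object@controls))
        paste0("[", paste(object@controls, collapse = ", "), "]") else "",
      "\n")
})

setMethod("show", "ScoreTrack", function(object) {
  cat("ScoreTrack:", length(object@sites), "markers;",
      "max raw score =", if (length(object@score)) max(object@score) else 0, "\n")
})

setMethod("show", "GenotypeGrid", function(object) {
  cat("GenotypeGrid:", nrow(object@states), "samples x",
      ncol(object@states), "markers;",
      sum(object@discordantSites), "discordant site(s)\n")
})
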