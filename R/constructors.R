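#' Construct a GenotypeMatrix
#'
#' Builds the bit-coded genotype store from a samples x sites character
#' matrix of genotype states and the site coordinates.  Sites must be SNVs
#' (single-base REF and ALT alleles) sorted by position within each
#' chromosome; chromosomes keep their order of first appearance, so no
#' particular karyotype is assumed.
#'
#' @param states character matrix (samples x sites) of genotype states; row
#'   names are the sample names unless \code{samples} is given.
#' @param chrom,pos,ref,alt per-site chromosome, 1-based position, reference
#'   allele and comma-separated alternate alleles; ignored when
#'   \code{sites} is supplied.
#' @param sites optionally a ready-made \code{GRanges} with \code{ref} and
#'   \code{alt} metadata columns.
#' @param samples character vector of sample names.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'   matrix(c("A", "HET", "A", "A"), nrow = 2,
#'          dimnames = list(c("S1", "S2"), NULL)),
#'   chrom = c("chr1", "chr1"), pos = c(100, 200),
#'   ref = c("A", "G"), alt = c("G", "A"))
#' genotypes(gm)
#' @export
GenotypeMatrix <- function(states, chrom = NULL, pos = NULL, ref = NULL,
                           alt = NULL, sites = NULL, samples = rownames(states)) {
  states <- as.matrix(states)
  if (is.null(samples))
    samples <- paste0("S", seq_len(nrow(states)))
  if (is.null(sites)) {
    sites <- GRanges(factor(chrom, levels = unique(chrom)),
                     IRanges(pos, pos))
    mcols(sites)$ref <- as.character(ref)
    mcols(sites)$alt <- as.character(alt)
  }
  if (ncol(states) != length(sites))
    stop("ncol(states) must equal the number of sites")
  new("GenotypeMatrix",
      packed = encodeGenotypeStates(as.vector(states)),
      samples = as.character(samples), sites = sites)
}

#' @describeIn GenotypeMatrix decode the full samples x sites state matrix.
#' @param x a \code{GenotypeMatrix}.
#' @param ... unused.
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x, ...) {
  m <- matrix(decodeGenotypeStates(x@packed,
                                   length(x@samples) * length(x@sites)),
              nrow = length(x@samples),
              dimnames = list(x@samples, NULL))
  m
})

#' Look up a single stored genotype state
#'
#' @param x a \code{GenotypeMatrix}.
#' @param sample sample name or row index.
#' @param siteIdx site column index (1-based).
#' @return the genotype state character, exactly as stored at ingest.
#' @export
genotypeAt <- function(x, sample, siteIdx) {
  stopifnot(is(x, "GenotypeMatrix"))
  i <- if (is.character(sample)) match(sample, x@samples) else as.integer(sample)
  if (anyNA(i) || any(i < 1L) || any(i > length(x@samples)))
    stop("unknown sample")
  ns <- length(x@samples)
  flat <- (as.integer(siteIdx) - 1L) * ns + i
  byte <- as.integer(x@packed[(flat - 1L) %/% 3L + 1L])
  slot3 <- (flat - 1L) %% 3L
  code <- (byte %/% c(1L, 6L, 36L)[slot3 + 1L]) %% 6L
  .GT_STATES[code + 1L]
}

#' Create an analysis configuration
#'
#' @param minRun minimum consecutive run-compatible markers per run
#'   (default 15).
#' @param coverageThreshold DP below which genotypes become NOCALL; 0
#'   disables (default 0).
#' @param scoreFraction relative-score threshold for candidate regions
#'   (default 0.6; markers strictly above it are flagged).
#' @param controlWeight weight of control runs in the score (default 1).
#' @param minPatients \code{"all"} (default) or an integer >= 1.
#' @param mode \code{"autozygous"} (patients share the same homozygous
#'   genotype; recommended within one family) or \code{"homozygous"} (any
#'   allele; for patients from different families).
#' @return an [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(minRun = 15L, coverageThreshold = 0L,
                           scoreFraction = 0.6, controlWeight = 1,
                           minPatients = "all",
                           mode = c("autozygous", "homozygous")) {
  mode <- match.arg(mode)
  mp <- if (identical(minPatients, "all")) NA_integer_
        else as.integer(minPatients)
  new("AnalysisConfig", minRun = as.integer(minRun),
      coverageThreshold = as.integer(coverageThreshold),
      scoreFraction = as.numeric(scoreFraction),
      controlWeight = as.numeric(controlWeight),
      minPatients = mp, mode = mode)
}

#' Create a sample manifest
#'
#' @param patients character vector of affected sample names (>= 1).
#' @param controls character vector of control sample names (optional;
#'   controls are not needed to determine runs of homozygosity).
#' @return a [SampleManifest-class] object.
#' @export
sampleManifest <- function(patients, controls = character()) {
  new("SampleManifest", patients = as.character(patients),
      controls = as.character(controls))
}

#' Validate a manifest against the samples present in a VCF
#'
#' @param manifest a [SampleManifest-class].
#' @param vcfSamples sample names from the VCF header.
#' @return the manifest, invisibly checked; errors name the offending
#'   samples and list the available candidates.
#' @export
validateManifest <- function(manifest, vcfSamples) {
  stopifnot(is(manifest, "SampleManifest"))
  all <- c(manifest@patients, manifest@controls)
  unknown <- setdiff(all, vcfSamples)
  if (length(unknown))
    .azStop("config", "unknown sample(s) in manifest: ",
            paste(unknown, collapse = ", "),
            "; VCF samples are: ", paste(vcfSamples, collapse = ", "))
  overlap <- intersect(manifest@patients, manifest@controls)
  if (length(overlap))
    .azStop("config", "overlapping roles for sample(s): ",
            paste(overlap, collapse = ", "))
  manifest
}

# Classed errors so the CLI can map them onto exit codes:
# az_config_error -> 2 (usage/config), az_data_error -> 1 (data).
.azStop <- function(kind = c("config", "data"), ...) {
  kind <- match.arg(kind)
  stop(structure(
    class = c(paste0("az_", kind, "_error"), "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))))
}
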