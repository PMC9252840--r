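#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @export
setGeneric("relScore", function(x) standardGeneric("relScore"))

#' Accessors for autozygR containers
#'
#' \code{sites()} returns the marker \code{GRanges}; \code{sampleNames()} the
#' sample names; \code{genotypes()} the decoded samples x sites character
#' matrix of genotype states; \code{score()} and \code{relScore()} the raw
#' and max-normalised homozygosity score vectors of a \code{ScoreTrack}.
#'
#' @param x a \code{GenotypeMatrix}, \code{ScoreTrack} or \code{GenotypeGrid}.
#' @param ... unused.
#' @return See details above.
#' @name accessors
#' @aliases sites sampleNames genotypes relScore
#'
#' @examples
#' gm <- GenotypeMatrix(
#'   matrix(c("A", "HET", "A", "A"), nrow = 2,
#'          dimnames = list(c("S1", "S2"), NULL)),
#'   chrom = c("chr1", "chr1"), pos = c(100, 200),
#'   ref = c("A", "G"), alt = c("G", "A"))
#' sampleNames(gm)
#' genotypes(gm)
NULL

setMethod("sites", "GenotypeMatrix", function(x) x@sites)
setMethod("sites", "ScoreTrack", function(x) x@sites)
setMethod("sites", "GenotypeGrid", function(x) x@sites)
setMethod("sampleNames", "GenotypeMatrix", function(x) x@samples)
setMethod("sampleNames", "GenotypeGrid", function(x) rownames(x@states))

#' @importFrom BiocGenerics score
setMethod("score", "ScoreTrack", function(x, ...) x@score)
setMethod("relScore", "ScoreTrack", function(x) x@relScore)

setMethod("dim", "GenotypeMatrix", function(x)
  c(length(x@samples), length(x@sites)))
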