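# VCF ingest: stream a multi-sample VCF into the bit-coded SNV genotype
# matrix plus a separate InDel table.  InDels are kept out of the mapping —
# their unbounded allele space defeats compact encoding and they are more
# prone to sequencing/alignment artefacts — but they are retained verbatim
# so that region-restricted VCF export can include them.

#' Read a multi-sample VCF into a GenotypeMatrix and an InDel table
#'
#' Every SNV record becomes one column of the genotype matrix, with states
#' from [classifyGenotype()] (applying the coverage rule from
#' \code{config}).  Records with multi-base or symbolic alleles are routed
#' to the InDel table and never enter the matrix.  The input must be
#' coordinate-sorted within each chromosome, as standard pipeline output
#' is; chromosomes are processed in order of first appearance so genomes of
#' any species work.
#'
#' @param path a VCF v4.x file, plain or bgzipped, with GT in FORMAT.
#' @param config an [analysisConfig()]; only \code{coverageThreshold} is
#'   used here.
#' @return a list with components \code{matrix} (a
#'   [GenotypeMatrix-class]), \code{indels} (data.frame of InDel records
#'   with the raw per-sample FORMAT strings), \code{samples} (VCF sample
#'   names) and \code{nRecords} (input record count).
#' @seealso [writeRegionVcf()] which restores InDels on export.
#' @export
readMultisampleVcf <- function(path, config = analysisConfig()) {
  stopifnot(is(config, "AnalysisConfig"))
  if (!file.exists(path))
    .azStop("data", "VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L)
    .azStop("data", "VCF has no per-sample genotype columns: ", path)
  fmt <- vcf@gt[, 1L]
  if (length(fmt) && !all(grepl("(^|:)GT(:|$)", fmt)))
    .azStop("data", "missing GT in FORMAT at record ",
            which(!grepl("(^|:)GT(:|$)", fmt))[1], " of ", path)
  samples <- colnames(vcf@gt)[-1L]

  chrom <- vcf@fix[, "CHROM"]
  pos <- as.numeric(vcf@fix[, "POS"])
  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  alt[is.na(alt)] <- "."
  nRecords <- length(pos)
  if (nRecords == 0L)
    .azStop("data", "no records in VCF: ", path)

  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p))
      .azStop("data", "unsorted positions within chromosome ", ch,
              "; a coordinate-sorted VCF is required")
  }

  altTokens <- strsplit(alt, ",", fixed = TRUE)
  isIndel <- nchar(ref) != 1L |
    !vapply(altTokens, function(a)
      all(nchar(a) == 1L & !grepl("[<>\\[\\]]", a)), logical(1))

  indels <- data.frame(chrom = chrom[isIndel], pos = pos[isIndel],
                       ref = ref[isIndel], alt = alt[isIndel],
                       stringsAsFactors = FALSE)
  if (any(isIndel))
    indels <- cbind(indels,
      as.data.frame(vcf@gt[isIndel, -1L, drop = FALSE],
                    stringsAsFactors = FALSE))

  snv <- which(!isIndel)
  if (!length(snv))
    .azStop("data", "no mappable sites: VCF contains no SNV records")

  key <- paste(chrom[snv], pos[snv])
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate SNV record(s) at the same (chrom, pos);",
            " keeping the first occurrence")
    snv <- snv[!dup]
  }

  gtm <- vcfR::extract.gt(vcf, element = "GT")
  dpm <- NULL
  if (config@coverageThreshold > 0L) {
    if (any(grepl("(^|:)DP(:|$)", fmt))) {
      dpm <- suppressWarnings(
        vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    } else {
      message("coverageThreshold > 0 but the VCF carries no per-sample DP; ",
              "all genotypes treated as above threshold")
    }
  }

  labels <- paste0(chrom[snv], ":", pos[snv])
  states <- matrix("NOCALL", nrow = length(samples), ncol = length(snv),
                   dimnames = list(samples, NULL))
  for (j in seq_along(samples)) {
    g <- gtm[snv, j]
    g[is.na(g)] <- "."
    dp <- if (is.null(dpm)) NA_real_ else dpm[snv, j]
    states[j, ] <- classifyGenotype(g, ref[snv], alt[snv], dp,
                                    config@coverageThreshold, site = labels)
  }

  gm <- GenotypeMatrix(states, chrom = chrom[snv], pos = pos[snv],
                       ref = ref[snv], alt = alt[snv], samples = samples)
  list(matrix = gm, indels = indels, samples = samples, nRecords = nRecords)
}
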