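# End-to-end pipeline: ingest -> runs -> shared regions -> (autozygosity
# refinement) -> score -> export -> plots.  Deterministic for fixed inputs
# and configuration; the resolved configuration is echoed to the output
# directory for reproducibility.

#' Run the full mapping pipeline
#'
#' Executes every stage on a multi-sample VCF and writes the region table
#' (TSV), region BED, region-restricted VCF, score bedGraph, the resolved
#' configuration (YAML) and, optionally, the genome-wide score plot and
#' the genotype grid of the top-ranked region.  Finding zero regions is a
#' valid outcome: the exports are then empty and a log line says so.
#'
#' @param vcf path to the multi-sample VCF (plain or gzipped).
#' @param manifest a [sampleManifest()] naming patients and optional
#'   controls.
#' @param config an [analysisConfig()].
#' @param outdir output directory (created if needed).
#' @param topN restrict the VCF export to the top-N regions by physical
#'   length; \code{NULL} exports all regions.
#' @param plots logical; render the score and grid images (default TRUE).
#' @return a list of class \code{"azPipelineResult"}: output paths,
#'   the region \code{GRanges}, the [ScoreTrack-class] and summary counts
#'   (input records, SNVs, InDels, regions, exported variants).
#' @export
runPipeline <- function(vcf, manifest, config = analysisConfig(),
                        outdir, topN = NULL, plots = TRUE) {
  stopifnot(is(manifest, "SampleManifest"), is(config, "AnalysisConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ing <- readMultisampleVcf(vcf, config)
  validateManifest(manifest, ing$samples)
  gm <- ing$matrix
  patients <- manifest@patients
  controls <- manifest@controls
  minPatients <- if (is.na(config@minPatients)) "all" else config@minPatients

  regions <- sharedRegions(gm, patients, minPatients, config@minRun)
  if (config@mode == "autozygous")
    regions <- autozygosityRefine(regions, gm, minRun = config@minRun)
  track <- scoreTrack(gm, patients, controls, config@controlWeight,
                      config@minRun)
  regions <- annotateRegionScores(regions, track)
  ranked <- rankRegions(regions)

  paths <- list(
    regions = file.path(outdir, "regions.tsv"),
    bed = file.path(outdir, "regions.bed"),
    vcf = file.path(outdir, "regions.vcf"),
    bedgraph = file.path(outdir, "score.bedgraph"),
    config = file.path(outdir, "config.yaml"))

  tab <- data.frame(
    chrom = as.character(seqnames(ranked)), start = start(ranked),
    end = end(ranked), bp_length = width(ranked),
    n_markers = mcols(ranked)$nMarkers, mode = mcols(ranked)$mode,
    patients = mcols(ranked)$patients,
    score_max = mcols(ranked)$scoreMax, stringsAsFactors = FALSE)
  utils::write.table(tab, paths$regions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeBed(ranked, paths$bed)
  nExported <- writeRegionVcf(vcf, ranked, paths$vcf, topN = topN)
  writeBedGraph(track, paths$bedgraph)
  yaml::write_yaml(list(
    minRun = config@minRun, coverageThreshold = config@coverageThreshold,
    scoreFraction = config@scoreFraction,
    controlWeight = config@controlWeight,
    minPatients = if (is.na(config@minPatients)) "all"
                  else config@minPatients,
    mode = config@mode, topN = topN,
    patients = patients, controls = controls), paths$config)

  if (plots) {
    paths$scorePlot <- file.path(outdir, "genome_scores.png")
    plotGenomeScores(track, config@scoreFraction, paths$scorePlot)
    if (length(ranked)) {
      top <- ranked[1]
      pad <- max(1L, round(0.1 * width(top)))
      q <- sprintf("%s:%d-%d", as.character(seqnames(top)),
                   max(1L, start(top) - pad), end(top) + pad)
      grid <- regionQuery(gm, q, patients = patients, controls = controls,
                          minRun = config@minRun)
      paths$gridPlot <- file.path(outdir, "region_grid.png")
      plotRegionGrid(grid, regionBox = top, paths$gridPlot)
    }
  }
  if (!length(ranked))
    message("no shared region found; exports are empty")

  structure(list(paths = paths, regions = ranked, track = track,
    summary = list(inputRecords = ing$nRecords,
      nSNV = length(sites(gm)), nIndel = nrow(ing$indels),
      nRegions = length(ranked), mode = config@mode,
      exportedVariants = nExported)),
    class = "azPipelineResult")
}

#' @export
print.azPipelineResult <- function(x, ...) {
  s <- x$summary
  cat("autozygR pipeline result (mode: ", s$mode, ")\n", sep = "")
  cat("  input records: ", s$inputRecords, " (", s$nSNV, " SNVs, ",
      s$nIndel, " InDels)\n", sep = "")
  cat("  regions found: ", s$nRegions, "\n", sep = "")
  cat("  variants exported: ", s$exportedVariants, "\n", sep = "")
  cat("  outputs in: ", dirname(x$paths$regions), "\n", sep = "")
  invisible(x)
}
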