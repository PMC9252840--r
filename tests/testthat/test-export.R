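mkRegion <- function(chrom, start, end, mode = "homozygous",
                     nMarkers = 20L, scoreMax = NA_real_) {
  gr <- GRanges(chrom, IRanges(start, end))
  mcols(gr)$startIdx <- 1L; mcols(gr)$endIdx <- nMarkers
  mcols(gr)$nMarkers <- nMarkers
  mcols(gr)$mode <- mode; mcols(gr)$patients <- "S1,S2"
  mcols(gr)$scoreMax <- scoreMax
  gr
}

test_that("BED export uses 0-based half-open coordinates and mode:rank names", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeBed(mkRegion("chr1", 1000, 2000, scoreMax = 0.8), path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_identical(fields[1:3], c("chr1", "999", "2000"))
  expect_identical(fields[4], "homozygous:1")
  expect_identical(fields[5], "800")

  # empty region list: empty file, no header
  writeBed(GRanges(), path)
  expect_length(readLines(path), 0L)
})

test_that("BED round-trip reproduces region bounds exactly", {
  set.seed(51)
  for (k in 1:20) {
    n <- sample(1:8, 1)
    start <- sort(sample(1e6, n)) * 10L
    gr <- suppressWarnings(do.call(c, lapply(seq_len(n), function(i)
      mkRegion(sample(c("chr1", "chr2"), 1), start[i],
               start[i] + sample(1e5, 1)))))
    path <- withr::local_tempfile(fileext = ".bed")
    writeBed(gr, path)
    bed <- read.table(path, sep = "\t",
                      col.names = c("chrom", "s", "e", "name", "score"))
    back <- GRanges(bed$chrom, IRanges(bed$s + 1L, bed$e))
    o1 <- order(as.character(seqnames(gr)), start(gr))
    o2 <- order(as.character(seqnames(back)), start(back))
    expect_identical(as.character(seqnames(gr))[o1],
                     as.character(seqnames(back))[o2])
    expect_identical(start(gr)[o1], start(back)[o2])
    expect_identical(end(gr)[o1], end(back)[o2])
  }
})

test_that("region VCF export keeps exactly the records inside the regions", {
  dir <- withr::local_tempdir()
  # 100 records, every 10th an InDel; one region covering positions 401-600
  n <- 100
  pos <- seq_len(n) * 10L
  ref <- rep("A", n); alt <- rep("G", n)
  indel <- seq_len(n) %% 10 == 0
  ref[indel] <- "AT"
  gt <- rbind(S1 = rep("0/0", n), S2 = rep(c("0/0", "1/1"), n / 2))
  path <- writeTinyVcf(file.path(dir, "in.vcf"), rep("chr1", n), pos,
                       ref, alt, gt)
  region <- mkRegion("chr1", 401, 600)
  out <- file.path(dir, "out.vcf")
  writeRegionVcf(path, region, out)
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  outPos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  # brute-force containment filter, InDels and discordant sites included
  expect_identical(outPos, pos[pos >= 401 & pos <= 600])
  expect_equal(length(body), 20L)
  ln500 <- strsplit(body[outPos == 500], "\t")[[1]]
  expect_identical(ln500[4], "AT")  # the InDel inside the region is exported
  # header preserved verbatim plus one provenance line
  inHdr <- readLines(path); inHdr <- inHdr[startsWith(inHdr, "#")]
  outHdr <- lines[startsWith(lines, "#")]
  expect_identical(setdiff(outHdr, inHdr),
                   grep("^##autozygR_regions=", outHdr, value = TRUE))
  expect_identical(outHdr[length(outHdr)], inHdr[length(inHdr)])

  # empty region list: header-only VCF
  writeRegionVcf(path, GRanges(), out)
  expect_true(all(startsWith(readLines(out), "#")))
})

test_that("region VCF export matches the per-record containment oracle", {
  set.seed(52)
  dir <- withr::local_tempdir()
  for (k in 1:15) {
    n <- sample(30:80, 1)
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
      sort(sample(1e5, length(i)))))
    names(pos) <- NULL
    path <- writeTinyVcf(file.path(dir, "r.vcf"), chrom, pos,
                         rep("A", n), rep("G", n),
                         rbind(S1 = rep("0/1", n)))
    nr <- sample(1:4, 1)
    regs <- suppressWarnings(do.call(c, lapply(seq_len(nr), function(i) {
      s <- sample(1e5, 1)
      mkRegion(sample(c("chr1", "chr2"), 1), s, s + sample(3e4, 1))
    })))
    out <- file.path(dir, "ro.vcf")
    suppressWarnings(writeRegionVcf(path, regs, out))
    body <- readLines(out); body <- body[!startsWith(body, "#")]
    keep <- vapply(seq_len(n), function(i)
      any(as.character(seqnames(regs)) == chrom[i] &
            start(regs) <= pos[i] & end(regs) >= pos[i]), logical(1))
    expect_equal(length(body), sum(keep))
    if (any(keep)) {
      got <- vapply(strsplit(body, "\t"), function(x)
        paste(x[1], x[2]), "")
      expect_identical(got, paste(chrom[keep], pos[keep]))
    }
  }
})

test_that("topN export restricts to the longest regions by physical length", {
  dir <- withr::local_tempdir()
  n <- 50
  pos <- seq_len(n) * 100L
  path <- writeTinyVcf(file.path(dir, "t.vcf"), rep("chr1", n), pos,
                       rep("A", n), rep("G", n), rbind(S1 = rep("0/0", n)))
  regs <- c(mkRegion("chr1", 100, 500), mkRegion("chr1", 2000, 4000))
  out <- file.path(dir, "to.vcf")
  writeRegionVcf(path, regs, out, topN = 1)
  body <- readLines(out); body <- body[!startsWith(body, "#")]
  outPos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_true(all(outPos >= 2000 & outPos <= 4000))  # only the longer region
})

test_that("regionQuery returns the genotype grid for coordinates and genes", {
  st <- randStates(3, 10, pHet = 0.3)
  gm <- mkMatrix(st)  # markers at 10 kb intervals
  grid <- regionQuery(gm, "chr1:15000-45000", minRun = 3)
  expect_s4_class(grid, "GenotypeGrid")
  expect_equal(ncol(grid@states), 3L)  # markers 2, 3, 4
  expect_identical(unname(grid@states), unname(st[, 2:4]))

  # gene query via annotation BED equals the coordinate query
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t14999\t45000\tMYGENE", bed)
  gridGene <- regionQuery(gm, "MYGENE", annotation = bed, minRun = 3)
  expect_identical(gridGene@states, grid@states)

  # a span with zero markers is an empty grid, not an error
  empty <- regionQuery(gm, "chr1:1-500", minRun = 3)
  expect_equal(ncol(empty@states), 0L)

  expect_error(regionQuery(gm, "MYGENE"), "annotation")
  expect_error(regionQuery(gm, "NOPE", annotation = bed), "not found")
})

test_that("grid discordance flags homozygous-different-allele sites", {
  st <- rbind(S1 = c("A", "A", "A", "HET"),
              S2 = c("A", "G", "NOCALL", "A"))
  gm <- mkMatrix(st)
  grid <- regionQuery(gm, "chr1:1-50000", patients = c("S1", "S2"),
                      minRun = 2)
  expect_identical(grid@discordantSites, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("highlighted markers in the genome plot equal the candidate set", {
  set.seed(53)
  st <- randStates(2, 120, pHet = 0.25)
  gm <- mkMatrix(st)
  tr <- scoreTrack(gm, rownames(st), minRun = 10)
  path <- withr::local_tempfile(fileext = ".png")
  hi <- plotGenomeScores(tr, scoreFraction = 0.6, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  cand <- candidateRegions(tr, 0.6, minRun = 1)
  candIdx <- unlist(lapply(seq_along(cand), function(r)
    mcols(cand)$startIdx[r]:mcols(cand)$endIdx[r]))
  expect_identical(sort(as.integer(hi)), sort(as.integer(candIdx)))

  # all-zero track: flat plot, file still created
  het <- matrix(rep("HET", 30), nrow = 1, dimnames = list("S1", NULL))
  trz <- scoreTrack(mkMatrix(het), "S1", minRun = 15)
  path2 <- withr::local_tempfile(fileext = ".png")
  expect_length(plotGenomeScores(trz, 0.6, path2), 0L)
  expect_true(file.exists(path2))
})

test_that("grid rendering: intensity grows with run length, bars mark discordance", {
  s1 <- c(rep("A", 10), "HET", rep("A", 3), rep("HET", 6))
  s2 <- c(rep("A", 9), "G", rep("A", 10))
  gm <- mkMatrix(rbind(S1 = s1, S2 = s2))
  grid <- regionQuery(gm, "chr1:1-300000", patients = c("S1", "S2"),
                      minRun = 3)
  path <- withr::local_tempfile(fileext = ".png")
  info <- plotRegionGrid(grid, path = path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # exactly one discordant column (marker 10: HOM A vs HOM G)
  expect_identical(info$discordantColumns, 10L)
  # S2's 20-marker run renders a stronger red than S1's 10-marker run
  rgb1 <- grDevices::col2rgb(info$colors[1, 1])  # run length 10
  rgb2 <- grDevices::col2rgb(info$colors[2, 1])  # run length 20
  expect_true(rgb2["green", 1] < rgb1["green", 1])

  # an all-HET grid renders uniformly in the heterozygous colour
  het <- matrix(rep("HET", 20), nrow = 1, dimnames = list("S1", NULL))
  gmh <- mkMatrix(het)
  gridh <- regionQuery(gmh, "chr1:1-300000", minRun = 3)
  infoh <- plotRegionGrid(gridh, path = withr::local_tempfile(fileext = ".png"))
  expect_equal(length(unique(as.vector(infoh$colors))), 1L)
})
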