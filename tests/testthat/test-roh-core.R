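test_that("findSampleRuns returns maximal run-compatible stretches >= minRun", {
  # 20 consecutive homozygous markers then a heterozygous one
  st <- matrix(c(rep("A", 20), "HET", rep("C", 5)), nrow = 1,
               dimnames = list("S1", NULL))
  runs <- findSampleRuns(mkMatrix(st), "S1", minRun = 15)
  expect_length(runs, 1L)
  expect_equal(mcols(runs)$nMarkers, 20L)
  expect_equal(mcols(runs)$startIdx, 1L)
  expect_equal(mcols(runs)$endIdx, 20L)
  expect_equal(mcols(runs)$nCalled, 20L)

  # two 14-marker stretches separated by a het marker: below threshold
  st2 <- matrix(c(rep("A", 14), "HET", rep("G", 14)), nrow = 1,
                dimnames = list("S1", NULL))
  expect_length(findSampleRuns(mkMatrix(st2), "S1", minRun = 15), 0L)

  # an all-heterozygous chromosome has no runs
  st3 <- matrix(rep("HET", 30), nrow = 1, dimnames = list("S1", NULL))
  expect_length(findSampleRuns(mkMatrix(st3), "S1", minRun = 15), 0L)

  # an all-NOCALL stretch is retained as a run (homozygous deletion)
  st4 <- matrix(c("HET", rep("NOCALL", 16), "HET"), nrow = 1,
                dimnames = list("S1", NULL))
  runs4 <- findSampleRuns(mkMatrix(st4), "S1", minRun = 15)
  expect_length(runs4, 1L)
  expect_equal(mcols(runs4)$nCalled, 0L)
})

test_that("runs never span chromosome boundaries", {
  st <- matrix(rep("A", 20), nrow = 1, dimnames = list("S1", NULL))
  gm <- mkMatrix(st, chrom = rep(c("chr1", "chr2"), each = 10),
                 pos = rep(seq_len(10) * 1000L, 2))
  runs <- findSampleRuns(gm, "S1", minRun = 5)
  expect_length(runs, 2L)
  expect_equal(as.character(seqnames(runs)), c("chr1", "chr2"))
  expect_equal(mcols(runs)$nMarkers, c(10L, 10L))
})

test_that("findSampleRuns matches the brute-force maximal-window oracle", {
  set.seed(31)
  for (k in 1:60) {
    n <- sample(20:200, 1)
    minRun <- sample(c(3, 5, 15), 1)
    st <- randStates(1, n, pHet = runif(1, 0.1, 0.6))
    runs <- findSampleRuns(mkMatrix(st), "S1", minRun)
    expect_equal(idxPairs(runs), unname(oracleRuns(st[1, ], minRun)),
                 ignore_attr = TRUE)
  }
})

test_that("sharedRegions intersects patients' runs at the marker level", {
  # identical runs in two patients collapse onto that run
  base <- c(rep("HET", 3), rep("A", 20), rep("HET", 3))
  st <- rbind(S1 = base, S2 = base)
  reg <- sharedRegions(mkMatrix(st), c("S1", "S2"), minRun = 15)
  expect_length(reg, 1L)
  expect_equal(mcols(reg)$startIdx, 4L)
  expect_equal(mcols(reg)$endIdx, 23L)
  expect_identical(mcols(reg)$mode, "homozygous")
  expect_identical(mcols(reg)$patients, "S1,S2")

  # disjoint runs with minPatients = all: nothing shared
  st2 <- rbind(S1 = c(rep("A", 20), rep("HET", 20)),
               S2 = c(rep("HET", 20), rep("A", 20)))
  expect_length(sharedRegions(mkMatrix(st2), c("S1", "S2"), minRun = 15), 0L)

  # overlapping runs at markers 1-40 and 21-60: shared part is 21-40
  st3 <- rbind(S1 = c(rep("A", 40), rep("HET", 20)),
               S2 = c(rep("HET", 20), rep("A", 40)))
  reg3 <- sharedRegions(mkMatrix(st3), c("S1", "S2"), minRun = 15)
  expect_equal(idxPairs(reg3), cbind(21L, 40L), ignore_attr = TRUE)

  expect_error(sharedRegions(mkMatrix(st3), c("S1", "S2"), minPatients = 3),
               "exceeds")
})

test_that("sharedRegions matches the per-marker support-count oracle", {
  set.seed(32)
  for (k in 1:40) {
    nsamp <- sample(2:5, 1)
    n <- sample(30:200, 1)
    minRun <- sample(c(5, 15), 1)
    kPat <- sample(nsamp, 1)
    st <- randStates(nsamp, n, pHet = runif(1, 0.1, 0.5))
    reg <- sharedRegions(mkMatrix(st), rownames(st), kPat, minRun)
    expect_equal(idxPairs(reg), unname(oracleShared(st, kPat, minRun)),
                 ignore_attr = TRUE)
  }
})

test_that("autozygosityRefine splits at allele-discordant sites", {
  # discordant interior marker: HOM(A) vs HOM(G) at site 20 of a 39-marker region
  s1 <- rep("A", 39)
  s2 <- rep("A", 39); s2[20] <- "G"
  st <- rbind(S1 = s1, S2 = s2)
  gm <- mkMatrix(st)
  hom <- sharedRegions(gm, c("S1", "S2"), minRun = 15)
  az <- autozygosityRefine(hom, gm, minRun = 15)
  expect_length(az, 2L)
  # the discordant marker belongs to neither sub-segment
  expect_equal(idxPairs(az), rbind(c(1L, 19L), c(21L, 39L)),
               ignore_attr = TRUE)
  expect_identical(unique(mcols(az)$mode), "autozygous")

  # fully concordant region passes through with mode flipped
  st2 <- rbind(S1 = rep("C", 20), S2 = rep("C", 20))
  gm2 <- mkMatrix(st2)
  hom2 <- sharedRegions(gm2, c("S1", "S2"), minRun = 15)
  az2 <- autozygosityRefine(hom2, gm2, minRun = 15)
  expect_equal(idxPairs(az2), idxPairs(hom2))

  # NOCALL wildcards restore concordance: single segment retained
  s3 <- rep("A", 20); s3[10] <- "NOCALL"
  s4 <- rep("A", 20); s4[15] <- "NOCALL"
  gm3 <- mkMatrix(rbind(S1 = s3, S2 = s4))
  hom3 <- sharedRegions(gm3, c("S1", "S2"), minRun = 15)
  az3 <- autozygosityRefine(hom3, gm3, minRun = 15)
  expect_length(az3, 1L)
  expect_equal(mcols(az3)$nMarkers, 20L)
})

test_that("refinement matches the brute-force concordance oracle", {
  set.seed(33)
  for (k in 1:40) {
    nsamp <- sample(2:4, 1)
    n <- sample(40:200, 1)
    minRun <- 5
    st <- randStates(nsamp, n, pHet = 0.15, pNocall = 0.1)
    gm <- mkMatrix(st)
    hom <- sharedRegions(gm, rownames(st), "all", minRun)
    az <- autozygosityRefine(hom, gm, minRun = minRun)
    expected <- NULL
    for (r in seq_along(hom))
      expected <- rbind(expected, oracleRefine(st, mcols(hom)$startIdx[r],
                                               mcols(hom)$endIdx[r], minRun))
    if (is.null(expected)) expected <- matrix(integer(0), ncol = 2)
    expect_equal(idxPairs(az), unname(expected), ignore_attr = TRUE)
  }
})

test_that("regions rank by physical length with marker-count tie-break", {
  gr <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(c(1e6, 5e6, 1e6), c(3e6, 10e6, 2e6)))
  mcols(gr)$startIdx <- c(1L, 10L, 30L)
  mcols(gr)$endIdx <- c(5L, 20L, 35L)
  mcols(gr)$nMarkers <- c(5L, 11L, 6L)
  mcols(gr)$mode <- "homozygous"
  mcols(gr)$patients <- "S1"
  mcols(gr)$scoreMax <- NA_real_
  ranked <- rankRegions(gr)
  expect_equal(width(ranked), sort(width(gr), decreasing = TRUE))
  expect_equal(mcols(ranked)$rank, 1:3)

  # tie on bp length: more markers first; then genomic order
  gr2 <- GRanges(c("chr2", "chr1"), IRanges(c(100, 100), c(1099, 1099)))
  mcols(gr2)$startIdx <- c(1L, 1L); mcols(gr2)$endIdx <- c(80L, 100L)
  mcols(gr2)$nMarkers <- c(80L, 100L)
  mcols(gr2)$mode <- "homozygous"; mcols(gr2)$patients <- "S1"
  mcols(gr2)$scoreMax <- NA_real_
  expect_equal(mcols(rankRegions(gr2))$nMarkers, c(100L, 80L))

  # randomized lists match a comparison-sort oracle
  set.seed(34)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    w <- sample(1e3:1e6, n)
    g <- GRanges("chr1", IRanges(sample(1e6, n), width = w))
    mcols(g)$startIdx <- seq_len(n); mcols(g)$endIdx <- seq_len(n)
    mcols(g)$nMarkers <- sample(10:100, n, replace = TRUE)
    mcols(g)$mode <- "homozygous"; mcols(g)$patients <- "S1"
    mcols(g)$scoreMax <- NA_real_
    o <- order(-width(g), -mcols(g)$nMarkers, start(g))
    expect_equal(idxPairs(rankRegions(g)), idxPairs(g[o]))
  }
})

test_that("autozygous segments are contained in their homozygous regions", {
  set.seed(35)
  tested <- 0L
  for (k in 1:25) {
    st <- plantShared(randStates(sample(2:4, 1), sample(60:150, 1),
                                 pHet = 0.2, pNocall = 0.1))
    gm <- mkMatrix(st)
    hom <- sharedRegions(gm, rownames(st), "all", 10)
    az <- autozygosityRefine(hom, gm, minRun = 10)
    if (!length(az)) next
    tested <- tested + 1L
    covered <- unlist(lapply(seq_along(hom), function(r)
      mcols(hom)$startIdx[r]:mcols(hom)$endIdx[r]))
    azIdx <- unlist(lapply(seq_along(az), function(r)
      mcols(az)$startIdx[r]:mcols(az)$endIdx[r]))
    expect_true(all(azIdx %in% covered))
  }
  expect_gt(tested, 10L)
})

test_that("lowering minPatients never shrinks the covered marker set", {
  set.seed(36)
  for (k in 1:15) {
    nsamp <- sample(3:5, 1)
    st <- randStates(nsamp, 120, pHet = 0.25)
    gm <- mkMatrix(st)
    cover <- function(kPat) {
      reg <- sharedRegions(gm, rownames(st), kPat, 10)
      unlist(lapply(seq_along(reg), function(r)
        mcols(reg)$startIdx[r]:mcols(reg)$endIdx[r]))
    }
    for (kPat in seq_len(nsamp - 1))
      expect_true(all(cover(kPat + 1) %in% cover(kPat)))
  }
})

test_that("sharedRegions with a single patient equals findSampleRuns", {
  set.seed(37)
  for (k in 1:15) {
    st <- randStates(1, sample(50:150, 1), pHet = 0.3)
    gm <- mkMatrix(st)
    runs <- findSampleRuns(gm, "S1", 15)
    reg <- sharedRegions(gm, "S1", "all", 15)
    expect_equal(idxPairs(reg), idxPairs(runs))
  }
})

test_that("hemizygous (all-homozygous) intervals surface as shared regions", {
  set.seed(38)
  st <- randStates(3, 100, pHet = 0.5)
  st[, 41:70] <- sample(HOMS, 3 * 30, replace = TRUE)  # forced homozygous
  gm <- mkMatrix(st)
  reg <- sharedRegions(gm, rownames(st), "all", 15)
  covered <- unlist(lapply(seq_along(reg), function(r)
    mcols(reg)$startIdx[r]:mcols(reg)$endIdx[r]))
  expect_true(all(41:70 %in% covered))
})
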