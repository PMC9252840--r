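# Fixture builders and independent brute-force oracles.  The oracles scan
# marker-by-marker with explicit loops and never share code with the
# package's rle/GRanges-based implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

HOMS <- c("A", "C", "G", "T")

# Build a GenotypeMatrix from a samples x sites character matrix; markers
# every 10 kb on one chromosome unless positions are given.
mkMatrix <- function(states, chrom = NULL, pos = NULL) {
  states <- as.matrix(states)
  n <- ncol(states)
  if (is.null(pos)) pos <- seq_len(n) * 10000L
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(rownames(states)))
    rownames(states) <- paste0("S", seq_len(nrow(states)))
  GenotypeMatrix(states, chrom = chrom, pos = pos,
                 ref = rep("A", n), alt = rep("G", n))
}

randStates <- function(nsamp, nsites, pHet = 0.3, pNocall = 0.05) {
  pHom <- (1 - pHet - pNocall) / 4
  m <- matrix(sample(c(HOMS, "HET", "NOCALL"), nsamp * nsites,
                     replace = TRUE,
                     prob = c(rep(pHom, 4), pHet, pNocall)),
              nrow = nsamp)
  rownames(m) <- paste0("S", seq_len(nsamp))
  m
}

# Overwrite a random interval with one shared homozygous base per site in
# every sample: a planted autozygous segment (plus optional NOCALLs).
plantShared <- function(st, minLen = 15, maxLen = 45, pNocall = 0.05) {
  n <- ncol(st)
  len <- min(n, sample(minLen:maxLen, 1))
  from <- sample(n - len + 1L, 1)
  cols <- from:(from + len - 1L)
  bases <- sample(HOMS, len, replace = TRUE)
  for (i in seq_len(nrow(st))) {
    st[i, cols] <- bases
    nc <- runif(len) < pNocall
    st[i, cols[nc]] <- "NOCALL"
  }
  attr(st, "planted") <- c(from, from + len - 1L)
  st
}

# Maximal stretches of TRUE of length >= minRun, by explicit scan.
oracleStretches <- function(flag, minRun) {
  out <- NULL
  i <- 1L
  n <- length(flag)
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1L]) j <- j + 1L
      if (j - i + 1L >= minRun) out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Per-sample runs: indices of maximal non-HET stretches (one chromosome).
oracleRuns <- function(stateRow, minRun) {
  oracleStretches(stateRow != "HET", minRun)
}

# Per-marker run membership for one sample.
oracleMembership <- function(stateRow, minRun) {
  runs <- oracleRuns(stateRow, minRun)
  mem <- logical(length(stateRow))
  if (nrow(runs)) for (r in seq_len(nrow(runs)))
    mem[runs[r, 1]:runs[r, 2]] <- TRUE
  mem
}

# Shared homozygous regions by per-marker support counting (one chromosome).
oracleShared <- function(states, minPatients, minRun) {
  support <- integer(ncol(states))
  for (i in seq_len(nrow(states)))
    support <- support + as.integer(oracleMembership(states[i, ], minRun))
  oracleStretches(support >= minPatients, minRun)
}

# Concordant sub-segments of a homozygous region across in-run patients.
oracleRefine <- function(states, regionStart, regionEnd, minRun) {
  idx <- regionStart:regionEnd
  mem <- t(sapply(seq_len(nrow(states)), function(i)
    oracleMembership(states[i, ], minRun)))
  conc <- vapply(idx, function(j) {
    obs <- states[mem[, j], j]
    obs <- obs[obs %in% HOMS]
    length(unique(obs)) <= 1L
  }, logical(1))
  segs <- oracleStretches(conc, minRun)
  if (nrow(segs)) segs + regionStart - 1L else segs
}

# Marker-index pairs (start, end) of a run/region GRanges, as a matrix.
idxPairs <- function(gr) {
  if (!length(gr)) return(matrix(integer(0), ncol = 2))
  unname(cbind(mcols(gr)$startIdx, mcols(gr)$endIdx))
}

# A tiny hand-rolled VCF writer for ingest/export fixtures.
writeTinyVcf <- function(path, chrom, pos, ref, alt, gt, dp = NULL,
                         samples = rownames(gt)) {
  header <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  fmt <- if (is.null(dp)) "GT" else "GT:DP"
  recs <- paste(chrom, pos, ".", ref, alt, ".", ".", ".", fmt, sep = "\t")
  for (i in seq_len(nrow(gt))) {
    fld <- if (is.null(dp)) gt[i, ] else paste0(gt[i, ], ":", dp[i, ])
    recs <- paste(recs, fld, sep = "\t")
  }
  writeLines(c(header, recs), path)
  path
}
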