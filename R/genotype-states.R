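# Genotype state model: six states, bit-coded storage, compatibility rules.
#
# A SNV genotype is one of four real-allele homozygous states (A, C, G, T),
# heterozygous (HET), or no-call (NOCALL).  Keeping the real allele of
# homozygous calls is what makes the autozygosity test possible: affected
# relatives who inherited the same segment identical-by-descent are
# homozygous for the *same* base, whereas unrelated patients may be
# homozygous for different bases.

.GT_STATES <- c("A", "C", "G", "T", "HET", "NOCALL")
.HOM_STATES <- c("A", "C", "G", "T")

#' The six genotype states
#'
#' Returns the state labels used throughout the package: the four
#' real-allele homozygous states \code{"A"}, \code{"C"}, \code{"G"},
#' \code{"T"}, plus \code{"HET"} and \code{"NOCALL"}.
#'
#' @return character vector of length 6.
#' @export
genotypeStates <- function() .GT_STATES

.stateCodes <- function(states) {
  codes <- match(states, .GT_STATES) - 1L
  if (anyNA(codes))
    stop("unknown genotype state: ",
         paste(unique(states[is.na(codes)]), collapse = ", "))
  codes
}

#' Pack and unpack genotype states
#'
#' Genotype states are stored bit-coded: with six states per genotype,
#' three genotypes fit in one byte (base-6 packing, 2.67 bits per
#' genotype).  \code{encodeGenotypeStates()} packs a state vector into a
#' raw vector; \code{decodeGenotypeStates()} restores it exactly.
#'
#' @param states character vector of genotype states (see
#'   [genotypeStates()]).
#' @param packed raw vector produced by \code{encodeGenotypeStates()}.
#' @param n number of genotypes originally packed.
#' @return \code{encodeGenotypeStates()}: a raw vector of length
#'   \code{ceiling(length(states)/3)}. \code{decodeGenotypeStates()}: the
#'   original character vector.
#' @examples
#' s <- c("A", "HET", "NOCALL", "T")
#' identical(decodeGenotypeStates(encodeGenotypeStates(s), 4), s)
#' @export
encodeGenotypeStates <- function(states) {
  codes <- .stateCodes(states)
  pad <- (3L - length(codes) %% 3L) %% 3L
  m <- matrix(c(codes, integer(pad)), nrow = 3L)
  as.raw(m[1L, ] + 6L * m[2L, ] + 36L * m[3L, ])
}

#' @rdname encodeGenotypeStates
#' @export
decodeGenotypeStates <- function(packed, n) {
  v <- as.integer(packed)
  codes <- c(rbind(v %% 6L, (v %/% 6L) %% 6L, v %/% 36L))
  .GT_STATES[codes[seq_len(n)] + 1L]
}

#' Classify VCF genotype calls into genotype states
#'
#' Maps per-sample GT values (with the site's REF/ALT alleles and optional
#' per-sample DP) to the six genotype states.  Two equal non-missing alleles
#' give the homozygous state of that base; two unequal alleles give HET; any
#' missing allele gives NOCALL.  A haploid call \code{"a"} (hemizygosity,
#' e.g. under a heterozygous deletion) is homozygous for that allele, so
#' hemizygous stretches are discovered like ordinary runs of homozygosity.
#' Genotypes whose DP falls below \code{coverageThreshold} become NOCALL
#' wildcards; this is what lets long homozygous deletions (no reads, no
#' call) surface as runs.  The phase separator \code{"|"} is treated exactly
#' like \code{"/"}.
#'
#' @param gt character vector of VCF GT values (\code{"a/b"}, \code{"a|b"},
#'   haploid \code{"a"}, or missing \code{"./."} / \code{"."}).
#' @param ref character vector of reference alleles (recycled).
#' @param alt character vector of comma-separated alternate alleles
#'   (recycled).
#' @param dp numeric vector of per-sample read depths; \code{NA} where DP is
#'   absent (absent DP is treated as above threshold).
#' @param coverageThreshold integer; DP below this becomes NOCALL. 0
#'   disables the rule.
#' @param site optional character labels (\code{"chrom:pos"}) used in error
#'   messages for malformed records.
#' @return character vector of genotype states, same length as \code{gt}.
#' @examples
#' classifyGenotype("1/1", ref = "A", alt = "G")                  # "G"
#' classifyGenotype("0/1", ref = "A", alt = "G", dp = 5,
#'                  coverageThreshold = 10)                       # "NOCALL"
#' classifyGenotype("0|0", ref = "C", alt = "T", dp = 50,
#'                  coverageThreshold = 10)                       # "C"
#' @export
classifyGenotype <- function(gt, ref, alt, dp = NA_real_,
                             coverageThreshold = 0L, site = NULL) {
  n <- length(gt)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  dp <- rep_len(as.numeric(dp), n)
  if (is.null(site)) site <- rep_len("?", n) else site <- rep_len(site, n)

  g <- chartr("|", "/", gt)
  nSlash <- nchar(g) - nchar(gsub("/", "", g, fixed = TRUE))
  if (any(nSlash > 1L))
    stop("malformed GT '", gt[which(nSlash > 1L)[1]], "' at ",
         site[which(nSlash > 1L)[1]])
  a1 <- sub("/.*$", "", g)
  a2 <- sub("^.*/", "", g)  # haploid call: a2 == a1, homozygous for it

  out <- rep("NOCALL", n)
  called <- a1 != "." & a2 != "."   # half-calls ("./1") stay NOCALL

  if (any(called)) {
    i1 <- suppressWarnings(as.integer(a1[called]))
    i2 <- suppressWarnings(as.integer(a2[called]))
    if (anyNA(i1) || anyNA(i2)) {
      bad <- which(called)[which(is.na(i1) | is.na(i2))[1]]
      stop("malformed GT '", gt[bad], "' at ", site[bad])
    }
    refc <- ref[called]
    altc <- alt[called]
    multi <- grepl(",", altc, fixed = TRUE)
    nalt <- rep(1L, sum(called))
    if (any(multi))
      nalt[multi] <- lengths(strsplit(altc[multi], ",", fixed = TRUE))
    if (any(i1 > nalt | i2 > nalt | i1 < 0L | i2 < 0L)) {
      bad <- which(called)[which(i1 > nalt | i2 > nalt | i1 < 0L | i2 < 0L)[1]]
      stop("allele index out of range in GT '", gt[bad], "' at ", site[bad])
    }
    resolve <- function(i) {
      b <- ifelse(i == 0L, refc, altc)
      sel <- multi & i > 0L
      if (any(sel))
        b[sel] <- mapply(function(a, k) a[k],
                         strsplit(altc[sel], ",", fixed = TRUE), i[sel],
                         USE.NAMES = FALSE)
      b
    }
    b1 <- resolve(i1)
    b2 <- resolve(i2)
    st <- ifelse(b1 == b2, toupper(b1), "HET")
    hom <- st != "HET"
    if (any(hom & !st %in% .HOM_STATES)) {
      bad <- which(called)[which(hom & !st %in% .HOM_STATES)[1]]
      stop("homozygous call for non-SNV allele in GT '", gt[bad], "' at ",
           site[bad])
    }
    out[called] <- st
  }

  if (coverageThreshold > 0L) {
    low <- !is.na(dp) & dp < coverageThreshold
    out[low] <- "NOCALL"
  }
  out
}

#' Run compatibility of a genotype state
#'
#' A marker extends a run of homozygosity unless it is heterozygous:
#' homozygous states of any base and no-calls are compatible.  Treating
#' no-calls as homozygous wildcards is deliberate — it keeps runs intact
#' across sparsely covered stretches and lets long homozygous deletions
#' (which yield no genotype calls) appear as runs.
#'
#' @param states character vector of genotype states.
#' @return logical vector: TRUE for homozygous and NOCALL states, FALSE for
#'   HET.
#' @examples
#' isRunCompatible(c("A", "HET", "NOCALL"))  # TRUE FALSE TRUE
#' @export
isRunCompatible <- function(states) {
  .stateCodes(states)  # validates
  states != "HET"
}

#' Allele concordance across samples at one site
#'
#' Tests whether a set of run-compatible genotype states is consistent with
#' all samples being homozygous for one shared haplotype (identity by
#' descent): every homozygous state must carry the same base, and NOCALL is
#' a wildcard compatible with any base.  An all-NOCALL set is vacuously
#' concordant.
#'
#' @param states character vector of genotype states; must all pass
#'   [isRunCompatible()].
#' @return single logical.
#' @examples
#' isAlleleConcordant(c("A", "A", "NOCALL"))  # TRUE
#' isAlleleConcordant(c("A", "G"))            # FALSE
#' @export
isAlleleConcordant <- function(states) {
  .stateCodes(states)
  if (any(states == "HET"))
    stop("isAlleleConcordant() requires run-compatible states; got HET")
  bases <- states[states != "NOCALL"]
  length(unique(bases)) <= 1L
}
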