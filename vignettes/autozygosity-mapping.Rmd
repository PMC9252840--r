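---
title: "Mapping shared homozygosity and autozygosity from multi-sample VCFs"
author: "autozygR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping shared homozygosity and autozygosity from multi-sample VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygR)
```

## The model

In a consanguineous family, an autosomal recessive disease allele is
usually inherited twice from one common ancestor. All affected
children are then homozygous not just for the disease variant but for
a whole chromosomal segment around it — the same haplotype, identical
by descent (IBD). The mapping problem is therefore an interval-finding
problem, not a statistical one: locate the maximal stretches of
markers where every patient is homozygous, and (within one family)
where they are homozygous for the *same* allele.

`autozygR` operates on a matrix of SNV genotype states, one of six per
sample and site: homozygous A, C, G or T, heterozygous (HET), or
missing (NOCALL). Keeping the real base of homozygous calls is what
separates the two analysis modes:

* **Homozygous mode.** A *run of homozygosity* for one sample is a
  maximal stretch of markers containing no HET call. A *shared region*
  is a maximal stretch at which at least `minPatients` patients
  (default: all) are inside one of their own runs. The haplotype is
  not compared, so this mode tolerates different disease haplotypes in
  patients from different families.
* **Autozygous mode.** Each shared homozygous region is refined by an
  allele-concordance test per site: among the patients in a run at
  that site, at most one distinct homozygous base may occur, with
  NOCALL acting as a wildcard. The region is split at every
  discordant site — the discordant marker belongs to neither
  sub-segment, since it marks the end of the IBD haplotype — and
  concordant sub-segments of at least `minRun` markers are reported.

Three conventions in the genotype model are deliberate and have
biological meaning:

1. **No-calls are run-compatible.** A NOCALL (missing GT, or DP below
   the coverage threshold) never interrupts a run. A long homozygous
   deletion produces exactly a stretch of no-calls, and this rule
   makes it surface as a run; a run may even consist of no-calls only
   (`nCalled == 0`).
2. **Haploid calls are homozygous.** Hemizygosity — e.g. one parental
   copy lost to a heterozygous deletion — yields haploid or
   homozygous-looking genotypes; such stretches are found like
   ordinary runs.
3. **InDels never enter the matrix.** Their allele space is unbounded
   (defeating the compact six-state encoding) and they are more prone
   to alignment artefacts. They are retained verbatim in a side table
   and reappear in the exported region VCF.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `minRun` | 15 | markers | minimum consecutive run-compatible markers per run, shared region and autozygous segment |
| `coverageThreshold` | 0 (off) | reads (DP) | genotypes with lower DP become NOCALL wildcards |
| `scoreFraction` | 0.6 | fraction of max | markers strictly above it form candidate regions / are highlighted |
| `controlWeight` | 1 | — | weight of control run lengths subtracted from the score |
| `minPatients` | all | patients | per-marker support needed for a shared region |
| `mode` | autozygous | — | `autozygous` within one family, `homozygous` across families |

`minRun = 15` exists to suppress spurious hits: a handful of
homozygous genotypes flanking a long stretch simply not covered in the
VCF would otherwise masquerade as a huge region. We apply the same
threshold to per-sample runs, shared regions and autozygous segments,
as it expresses a property of what deserves to be called a run at
all. The coverage threshold defaults to off because a sensible value
depends on the sequencing platform; 10 is a reasonable choice for
standard short-read data. When DP is absent from a VCF that is
analysed with a positive threshold, genotypes are treated as above
threshold (and this is logged once) rather than silently discarded.

## The homozygosity score

The per-marker raw score is

$$S(m) = \max\!\Big(0,\; \sum_{p \in \text{patients}} L_p(m) \;-\; w
\sum_{c \in \text{controls}} L_c(m)\Big)$$

where $L_s(m)$ is the marker length of sample $s$'s run enclosing $m$
(0 outside every run) and $w$ the control weight. Summing enclosing-run
*lengths* makes long runs shared by many patients tower over short
private ones, and a control sharing the same run pulls the region
down. The relative score $R = S / \max S$ is normalised over the whole
genome — one natural 100% peak — and candidate regions are the maximal
stretches with $R$ *strictly* above `scoreFraction`. The score is a
display and ranking device: it carries no significance statement, and
the package intentionally computes no LOD score or homozygosity
statistic (tools like PLINK or AutoMap serve that need).

Regions themselves are ranked by **physical length in bp** (positions
of the first and last supporting markers, both inclusive), with marker
count and genomic position as tie-breaks. Marker count alone would
favour densely covered regions; physical length is what matters for a
segment's genetic interpretation.

## Numerical and boundary choices

* Region bp bounds are the positions of the first and last supporting
  markers. No extension toward flanking heterozygous markers (e.g. to
  interval midpoints) is applied; boundaries are at marker
  granularity.
* The discordant site in autozygosity refinement is excluded from both
  flanking sub-segments.
* `scoreFraction` comparison is strict (`>`), so a fraction of 1 never
  selects anything.
* Supporting patients of a region are those whose runs overlap it.
  With `minPatients = "all"` (the default) every supporter spans the
  whole region and the concordance test reduces to the plain per-site
  comparison across all patients. With a relaxed `minPatients`,
  overlapping runs of different patients can form a "staircase" in
  which no single patient spans the region; concordance is then tested
  per site among the patients actually in a run there.
* Ties in genotype storage: duplicate `(chrom, pos)` SNV records keep
  the first occurrence (with a warning); input must be
  coordinate-sorted per chromosome, as standard pipeline output is,
  and chromosomes are processed in order of first appearance — no
  karyotype is assumed, so non-human genomes work.
* An all-zero score track has no defined relative score; it is
  reported as all zeros and yields no candidate regions.
* The six genotype states are bit-coded base-6, three genotypes per
  byte (2.67 bits/genotype); `decode(encode(x)) == x` is tested
  exhaustively.

## What the simulator emulates — and what it does not

`simSpec()`/`simulateVcf()` generate the study design the method
targets: a multi-sample VCF of biallelic SNVs with per-sample `GT:DP`.
Defaults describe a consanguineous quartet — two affected siblings and
their parents, 20,000 polymorphic SNVs on two 120 Mb chromosomes, one
planted 500-marker autozygous segment shared by the sibs, 2% no-call,
low-coverage and InDel rates, allele frequencies Uniform(0.05, 0.5)
(polymorphic sites are the informative ones for ROH detection), and
Poisson(30) depth. Planted segment types cover the four phenomena the
genotype model must handle: `autozygous_shared` (one haplotype, all
carriers homozygous for it), `homozygous_discordant` (independent
haplotypes per carrier), `hemizygous` (haploid GT) and
`homozygous_deletion` (missing GT, DP 0).

Not modelled, deliberately: linkage disequilibrium, recombination
maps, exome capture clustering (sites are uniform along the
chromosome), and pedigree-consistent parental genotypes (parents
receive ordinary Hardy–Weinberg draws). Passing the recovery tests
therefore demonstrates the interval logic — detection, refinement,
ranking, export — under realistic marker density and noise, not
robustness to LD-induced chance homozygosity, which in real data is
exactly what the 15-marker threshold and physical-length ranking
mitigate.

Simulation sizes used in the test suite are scaled to the question
each test asks: exhaustive oracle comparisons run on matrices up to
5 × 500 (where brute-force enumeration is feasible), recovery and
mode-discrimination checks on 2,000–20,000-site simulations across
dozens of seeds, and the variant-reduction check on a 50,000-variant
simulation with a planted segment covering ~1% of markers.

## Coordinates and formats

Internally everything is 1-based inclusive (VCF convention); GRanges
carry both bp bounds and marker-index bounds (`startIdx`, `endIdx`).
BED and bedGraph exports use the 0-based half-open convention; the
region VCF export filters records by POS only (an InDel starting
before a region boundary is kept only if its POS lies inside — record
level filtering, deterministic and faithful to what downstream tools
re-parse), preserves the input header verbatim and adds one
`##autozygR_regions=` provenance line.

## Known limitations

* Genotype likelihoods (PL/GL) are ignored; only GT and DP are read.
* No phasing-aware IBD inference and no pedigree likelihoods: allele
  concordance at homozygous sites is the entire IBD criterion.
* The score has no null model; relative peaks are comparable within an
  analysis, not across datasets.
* Because the score sums each patient's own enclosing-run length — a
  run that may extend beyond the shared region — the score peak and
  the bp-longest region can disagree when several regions compete.
  With one dominant shared segment (the typical consanguinity case)
  the top-ranked region carries the 100% peak.
* SNP-array genotype files are out of scope; input is VCF only.
* The region VCF export keys on POS, so a structural variant whose
  span overlaps a region but whose POS precedes it is not exported.
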