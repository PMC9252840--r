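# autozygR

Homozygosity and autozygosity mapping from multi-sample VCF files, in R.

## The problem

Autosomal recessive disease in consanguineous families is classically
mapped by homozygosity: affected children are likely to have inherited
the same disease allele in homozygous state from a common ancestor, so
the causal variant lies inside a long run of homozygosity (ROH) shared
by all patients. With exome/genome sequencing, restricting the variant
list to such shared regions — the "positional candidates" — typically
shrinks it by around two orders of magnitude before any functional
filtering starts.

`autozygR` finds these regions directly from a multi-sample VCF, with no
pre-processing. Because it stores SNV genotypes with their **real
alleles** (four distinguishable homozygous states A/C/G/T, plus HET and
NOCALL, bit-coded three genotypes per byte), it distinguishes two
questions:

* **homozygous mode** — at every marker, are all (or at least *k*)
  patients inside a run of homozygosity, whatever the allele? Suitable
  for patients from different families.
* **autozygous mode** — are the patients homozygous for the *same*
  base, consistent with one haplotype inherited identical by descent?
  Recommended within a single family. A site where patients carry
  homozygous genotypes for different alleles terminates the autozygous
  segment.

Three deliberate conventions drive the genotype model:

* no-calls and genotypes below a coverage threshold are treated as
  homozygous wildcards, so long homozygous deletions (no reads, no
  calls) surface as runs;
* haploid GT values (hemizygosity, e.g. under a heterozygous deletion)
  count as homozygous;
* InDels never take part in the mapping (unbounded allele space,
  alignment artefacts) but are kept aside and re-appear in the exported
  region VCF.

A run requires at least 15 consecutive run-compatible markers (guarding
against a few homozygous genotypes flanking an uncovered stretch), and
regions are ranked by their physical length in bp, not marker count.

The per-marker homozygosity score is

    S(m) = max(0, Σ_patients L_p(m) − w · Σ_controls L_c(m))

where `L_s(m)` is the length (in markers) of sample *s*'s run enclosing
marker *m* (0 outside any run) and `w` the control weight. The relative
score `R = S / max(S)` is normalised genome-wide; markers with `R`
above a fraction of the maximum (default 60%) form the candidate
regions highlighted in the genome plot. No statistical significance or
LOD score is computed — by design.

## Worked example

```r
library(autozygR)

## a consanguineous quartet: 2 affected sibs, 2 parents, 20,000 SNVs,
## one planted 500-marker autozygous segment (the simulator's defaults)
sim <- simulateVcf(simSpec(seed = 7), "quartet.vcf")

res <- runPipeline("quartet.vcf",
  sampleManifest(c("Patient1", "Patient2"), c("Father", "Mother")),
  analysisConfig(mode = "autozygous"),
  outdir = "out")
print(res)
#> autozygR pipeline result (mode: autozygous)
#>   input records: 20000 (19600 SNVs, 400 InDels)
#>   regions found: 1
#>   variants exported: 500
#>   outputs in: out

res$regions
#> GRanges object with 1 range and 7 metadata columns:
#>       seqnames            ranges strand |  startIdx    endIdx  nMarkers
#>   [1]     chr1 48283332-54086948      * |      3912      4404       493
#>             mode          patients  scoreMax      rank
#>   [1]  autozygous Patient1,Patient2         1         1

truthOverlap(res$regions, sim$truth)
#> [1] 1
```

The one detected autozygous region covers the planted segment exactly
(reciprocal overlap 1; 493 of the 500 planted sites remain SNV markers
after InDel conversion and the region's 500 exported variants include
the InDels inside it). The exported `out/regions.vcf` holds 500 of the
20,000 input variants — 2.5%, ready for a disease-mutation search
engine. `out/` also holds the region table
(TSV), a BED file of the regions (0-based half-open, ranked by physical
length), the score track as bedGraph, the genome-wide score plot and
the genotype grid of the top region.

The same pipeline is available from the shell:

```sh
Rscript inst/scripts/autozygr.R simulate --out quartet.vcf --seed 7
Rscript inst/scripts/autozygr.R run --vcf quartet.vcf \
    --patients Patient1,Patient2 --controls Father,Mother --out out
```

Exit codes: 0 success (including "no region found"), 2 usage/config
error, 1 data error.

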