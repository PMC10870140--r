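# hstkit

Haplotype sharing trees and ancestral haplotype analysis for phased
biallelic genotype data.

Around a founder mutation — the motivating case is a pathogenic repeat
expansion such as the *C9orf72* GGGGCC expansion in ALS/FTD — carrier
chromosomes retain nested, progressively recombined copies of the founder
haplotype. `hstkit` is for geneticists who have a phased cohort VCF around
such a locus and want to:

- build **haplotype sharing trees** (HSTs): starting from a focal marker,
  haplotypes are scanned outward (one direction, `build_uhst()`, or both at
  once, `build_bhst()`) and split whenever contradictory alleles appear, so
  every node stores a continuously shared haplotype and the rows carrying
  it, with the largest child always leftmost;
- derive the **majority-based ancestral haplotype** (the haplotype of the
  deepest ≥2-sample node on the majority branch — a proxy for the founder)
  and the **core haplotype** shared by all carriers;
- **select the carrier haplotype** of each sample (the one sharing the
  longer ancestral segment) and **flag suspected phasing switch errors**;
- estimate the age of the most recent common ancestor with the **gamma
  method**: per-haplotype shared-segment lengths l_i (Morgans, via a PLINK
  genetic map) are modelled as sums of Exponential(τ) side lengths, giving
  τ̂ = (2n−1)/Σl_i with gamma-quantile confidence bounds under a star
  genealogy, plus a correlated-genealogy mode with moment-matched effective
  shape 2n/(1+(n−1)ρ);
- analyse sharing by **repeat-length class** (bins 2–6, 7–9, 10–14, 15–19,
  20–45), compare external cohorts to published haplotypes and **anonymized
  HSTs** (`.hst.gz` gzipped JSON, lossless round trip), and
- **simulate** founder cohorts with known truth (`simulate_cohort()`) to
  validate every step end to end.

## Worked example

A simulated founder cohort: 150 carrier samples, 1,500 markers spanning
30 Mb, founder age τ = 40 generations.

```r
library(hstkit)

sim <- simulate_cohort(n_carriers = 150, n_markers = 1500,
                       spacing_bp = 2e4, tau = 40, seed = 11)
hm  <- sim$matrix            # or read_phased_vcf("cohort.vcf.gz")
idx <- sim$focal_idx         # or marker_at(hm, pos, "upstream")

anc <- merge_ancestral(
  ancestral_haplotype(build_uhst(hm, idx, "left")),
  ancestral_haplotype(build_uhst(hm, idx, "right")),
  start_pos = hm$variants$pos[idx])
anc
#> Haplotype of 1298 markers, 1 : 2060000 - 28000000 ( 25940000 bp )

carriers <- select_carrier_haplotypes(hm, anc, idx)   # one row per sample
build_bhst(carriers, idx)
#> Haplotype sharing tree (bidirectional)
#>   242 nodes (150 leaves), 150 haplotypes
#>   start marker: #750 at 1:15000000

segs <- shared_segments(carriers, anc, idx)
segs <- segment_genetic_lengths(segs, sim$map, sim$locus_pos)
mean(segs$bp_len) / 1e6
#> [1] 5.22

estimate_mrca(segs$l_morgans, mode = "independent")
#> MRCA estimate (gamma method, independent genealogy)
#>   tau = 38.2 generations, 95% CI [34.1, 42.8]
#>   n = 150 haplotypes, sum(l) = 7.8310 Morgans
```

The merged ancestral haplotype spans the 25.9 Mb jointly retained by the
two deepest-sharing carriers; selection recovers the true carrier strand
for all 150 samples (the truth is in `sim$truth`); and the gamma estimate
38.2 (34.1–42.8) brackets the simulated τ = 40. At 25 years per
generation that is 955 years (852–1,069, 95% CI)
(`generations_to_years()`).

The methods vignette (`vignettes/haplotype-sharing-trees.Rmd`) documents
the algorithms, the tie-break and breakpoint conventions, the
correlated-genealogy derivation, and what the simulator does and does not
emulate.

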