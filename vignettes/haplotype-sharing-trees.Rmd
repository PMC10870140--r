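---
title: "Haplotype sharing trees: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype sharing trees: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hstkit)
```

## The problem

Around a disease locus — the motivating case is a pathogenic repeat
expansion such as the GGGGCC hexanucleotide expansion implicated in ALS and
frontotemporal dementia — carrier chromosomes in a founder population
descend from a small number of ancestral haplotypes. Two questions follow:
*which* haplotype did the mutation arise on, and *how long ago*?
Recombination answers both: each meiosis since the common ancestor has had a
chance to shorten the stretch of ancestral sequence around the locus, so the
population of carrier haplotypes today carries nested, progressively shorter
copies of the founder haplotype. The haplotype sharing tree (HST) is a data
structure that makes this nesting explicit, and the gamma method converts
the lengths of the retained stretches into an age in generations.

All inputs are phased, biallelic genotype matrices: one row per phased
haplotype, one column per SNP marker, alleles coded 0/1, positions 1-based
and strictly increasing on a single contig. Phasing quality matters —
switch errors create chimeric rows — which is why the package also flags
suspected switch errors (it never corrects them; see below).

## Tree construction

Both builders start from a focal marker (`marker_at()` picks the marker at,
or nearest to, a base-pair coordinate; the default policy takes the closest
marker *upstream*, matching the convention of anchoring just before a
repeat locus that is itself not genotyped on arrays).

**Unidirectional** (`build_uhst()`): scan column by column away from the
start marker, one direction at a time. Columns where all rows of the
current node agree extend the node's shared haplotype; the first column
carrying both alleles splits the node into two children, each inheriting
the shared haplotype plus the contradictory marker with its own allele.
**Bidirectional** (`build_bhst()`): each node scans left and right
simultaneously, absorbing uniform columns on both sides until a
contradictory column is found on *each* side; rows are then partitioned by
their (left allele, right allele) pair into two to four children. If one
side has run out of markers, a two-way split on the remaining side is
performed, so trees extend to the contig ends. In both builders a node
stops branching when it holds one row, fewer than `min_size` rows, or the
data end is reached; the root always holds every row and an empty
haplotype.

Ordering is part of the algorithm's contract, because the *leftmost* child
defines the majority branch. The larger child always comes first. The
original description is silent about ties, so the package fixes them
deterministically: on equal sizes the child with allele 0 at the split
marker comes first (for bidirectional splits, the lexicographically smaller
(left, right) allele pair). `min_size` doubles as the visualisation stop
and the privacy filter used before publishing trees (`prune_anonymize()`
removes nodes below a size threshold and can strip all sample
identification, keeping counts only).

Recursion is implemented as an explicit FIFO queue, not R-level recursion,
so deep majority chains on large cohorts cannot hit the interpreter's stack
limit. Column scans run in chunks of 256 columns so that a node never
touches markers beyond its own split.

Multiallelic records are rejected at input rather than auto-split.
Sequential branching over multiallelic alleles depends on VCF record order,
which silently changes tree shape; demanding an explicit upstream
`bcftools norm -m -` keeps results reproducible.

## Ancestral, core and carrier haplotypes

Following the largest child at every step walks recombination events back
in time; the haplotype of the deepest node on that path still shared by two
or more rows is the **majority-based ancestral haplotype**
(`ancestral_haplotype()`), the package's proxy for the founder haplotype.
For unidirectional trees the two per-side haplotypes are merged
(`merge_ancestral()`); both sides include the start marker, which makes the
merge overlap-checkable, and any conflicting overlapping allele is an
error. The **core haplotype** (`core_haplotype()`) is the maximal
contiguous marker run through the start marker on which *every* row agrees
— empty as soon as the start column itself is polymorphic.
`hst_shared_core()` recovers the same run from a tree alone (the markers on
which all of the root's children agree), which is what makes the check
possible on published, anonymized trees without genotypes.

Carrier selection (`select_carrier_haplotypes()`) keeps, per sample, the
phased haplotype sharing the longer ancestral segment. Sharing is measured
in contiguous *markers* with base-pair length as tie-break: marker counts
are robust to marker density, and the remaining ties (both rows equal)
keep the first haplotype with a warning. Whether the original selection
metric was markers, bp or cM is not documented; the metric is exposed as a
flag (`metric = "markers"` or `"bp"`), and both lengths are always carried
in the `shared_segments()` output.

## Switch-error flagging

A run of ancestral-matching markers *beyond* a haplotype's breakpoint is
unlikely under genuine recombination — at background allele frequencies a
chance match dies off geometrically — and usually marks a phasing switch
or a genotyping error. `flag_switch_errors()` reports every maximal run of
at least `min_run` consecutive matches beyond either breakpoint. The
default `min_run = 20` markers is far above chance matching at typical
array densities (at a matching probability of one half per marker, a
20-marker run has probability on the order of 1e-6 per position) while
staying short enough to catch switches near the locus. Flags are reports,
never corrections: the majority-based ancestral haplotype is already
robust to isolated switches, and rephasing individual samples would
manufacture data.

## MRCA estimation with the gamma method

For each selected carrier haplotype the breakpoints of its shared segment
are translated to centimorgans by linear interpolation in a PLINK-format
genetic map (`interpolate_cM()`; positions outside the map clamp to the
terminal cM values) and summed into a per-haplotype genetic length
\(l_i\) in Morgans (`segment_genetic_lengths()`; the cM-to-Morgan division
by 100 happens in exactly this one place). The breakpoint is the first
*mismatching* marker on each side, a deliberate convention: using the last
matching marker would understate segment length at low marker density,
while the first mismatch brackets the true recombination point from
outside. Rows whose sharing runs into the data end are flagged censored
but kept, since the method is applied without any chance-sharing
correction; at the marker spans used in practice the resulting bias is
small (see the simulator notes).

Under a star genealogy each side length is Exponential(\(\tau\)) in the
number of generations \(\tau\) to the common ancestor, so
\(S = \sum_i l_i\) over \(n\) haplotypes is Gamma\((2n, \tau)\). The
bias-corrected point estimate and CI are

\[\hat\tau = \frac{2n - 1}{S}, \qquad
\left[\frac{q_{\Gamma(2n,1)}(\alpha/2)}{S},\;
      \frac{q_{\Gamma(2n,1)}(1-\alpha/2)}{S}\right].\]

Real genealogies are not stars: lineages share part of their path to the
MRCA, so segment lengths are positively correlated and the star CI is too
narrow. The package's correlated mode models this with a pairwise
correlation \(\rho\) between per-haplotype lengths. Writing each side
length as the minimum of a shared-path and a private-path exponential,
\(y_i = \min(T_{\mathrm{shared}}, T_i)\) with the shared path a fraction
\(s\) of the total, gives
\(\operatorname{cor}(y_i, y_j) = s / (2 - s)\); a balanced deep genealogy
with mean shared fraction \(s = 1/2\) yields the default
\(\rho = 1/3\). Matching the first two moments of \(S\) — mean \(2n/\tau\),
variance \((2n/\tau^2)(1 + (n-1)\rho)\) — to a gamma distribution gives an
effective shape \(k = 2n / (1 + (n-1)\rho)\) and

\[\hat\tau = \frac{2n(k-1)}{kS}, \qquad
\left[\frac{2n\,q_{\Gamma(k,1)}(\alpha/2)}{kS},\;
      \frac{2n\,q_{\Gamma(k,1)}(1-\alpha/2)}{kS}\right],\]

which reduces *exactly* to the independent form at \(\rho = 0\) (a tested
property). For large \(n\) the effective shape tends to \(2/\rho\): the
information in a correlated cohort saturates, which is why published
correlated-genealogy intervals stay wide even for hundreds of carriers.
The independent mode is the default and the one pinned by parameter
recovery simulations; the correlated mode is validated for its limit
behaviour and for improved coverage on simulated two-clade genealogies.
Neither mode applies a chance-sharing correction. Years are obtained by
multiplying generations by `years_per_generation` (25 by convention).

## Cross-cohort comparisons

Comparing a cohort genotyped on one array with a haplotype or tree from
another requires marker harmonisation (`intersect_markers()`): markers are
matched on (contig, position); identical ref/alt pairs pass through;
swapped ref/alt pairs are rescued by inverting the allele code; and
strand-ambiguous A/T and C/G markers are dropped, because their strand
cannot be resolved across arrays. `cohort_to_haplotype()` then computes
shared segments on the intersection (reporting the intersection size —
lengths in markers refer to the intersected set, lengths in Mb to
breakpoint positions), and `cohort_to_hst()` counts, for every non-root
node of a published tree, how many query haplotypes are consistent with
the node haplotype restricted to the shared markers. A node whose
restricted haplotype is empty matches vacuously and is flagged
uninformative; the root has no haplotype and is reported as not
applicable. When sibling nodes coincide after restriction both count the
same rows — exactly the behaviour expected when the differentiating
markers are missing from the query array.

`group_sharing()` buckets samples by their largest repeat allele into the
conventional bins 2–6, 7–9, 10–14, 15–19 and 20–45 (the bins are
arguments; a discrete mode makes one group per repeat length). The mean
segment length per bin can include all haplotypes of the bin's samples or
only the selected longer-sharing ones — both views are published in this
literature, so the choice is a flag (`use`), defaulting to all. Per-bin
MRCA estimates always use the selected haplotypes.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates the exact inheritance model the gamma method
assumes: a founder haplotype drawn from per-marker background frequencies
(uniform on [0.05, 0.95] by default), `n_carriers` copies truncated at
per-side breakpoints whose genetic distances from the focal locus are
Exponential(`tau`), a uniform recombination map (1 cM/Mb by default, so
analytic expectations are exact and an arbitrary map can be substituted to
exercise interpolation), background diploid controls, and optional planted
switch errors that swap a sample's strand suffixes at a recorded marker.
Everything derives from one seed, and the truth (founder haplotype,
per-carrier breakpoints, switch positions) is returned and written next to
the VCF.

Two idealisations matter for interpreting green tests. First, background
markers are independent — there is no linkage disequilibrium — so chance
sharing between unrelated haplotypes is minimal, matching the regime in
which the gamma method is applied without chance-sharing correction but
understating the segment lengths a real population panel would show around
a common haplotype. Second, the recombination map is uniform unless a real
map is supplied, so map-interpolation error is exercised only by the
dedicated tests. Passing the recovery suites therefore demonstrates
correctness of the algorithms under their stated model, not robustness to
LD-induced chance sharing or fine-scale recombination-rate variation.

## Numerical and scale choices

Test and validation scales were chosen to finish in minutes on one core
while keeping Monte-Carlo error well inside the asserted bands: 100 random
50×200 cohorts for the oracle-equivalence sweep, 50 replicates of 200
carriers × 2,000 markers for founder recovery, and 500 replicates of
n = 100 at τ = 50 for estimator recovery (mean \(\hat\tau/\tau\) asserted
within 5%, empirical CI coverage within [0.92, 0.975]). The end-to-end
pipeline test uses a 24 Mb marker span so that end-censoring of segments
(which inflates \(\hat\tau\) by roughly \(1/(1 - e^{-\tau G})\) for a
per-side genetic span \(G\)) stays under a few percent. Degenerate inputs
are first-class: single-row matrices, all-identical cohorts, start markers
at the matrix edge, rows mismatching at the start marker (zero-length
segments with both breakpoints at the start position), and empty repeat
bins all have defined, tested behaviour.

## File formats

Phased VCF/VCF.gz is read through `vcfR`, with strict validation (any
unphased, missing, non-diploid or multiallelic GT is an error naming the
record and sample). Genetic maps use the PLINK 4-column dialect
(chrom, id, cM, bp), parsed strictly — monotone cM, one contig per file —
rather than sniffing dialects. Haplotypes travel as
`contig,pos,id,ref,alt,allele` CSVs. Trees are serialised as gzipped JSON
(`.hst.gz`) with 0-based node ids, marker indexes and row indexes on disk;
reading tolerates plain JSON and preserves unknown extra fields, a
deliberate margin for trees produced by other implementations whose exact
schema may drift. Anonymized files carry node counts but no sample
identifiers, and a round trip is lossless for every schema field.

## Known limitations

Bidirectional trees are shaped more by whichever side recombined earlier,
and uneven marker density left and right of the locus biases their
structure; for MRCA estimation the unidirectional trees are the supported
path. The correlated-genealogy correction uses a single exchangeable
correlation rather than a genealogy inferred from the data. Chance-sharing
correction is out of scope by design, as is any multiallelic branching,
re-phasing, imputation or BCF support.
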