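---
title: "Decontaminating MAG bins: methods and design notes"
author: "magrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decontaminating MAG bins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magrefine)
```

# The problem

Metagenome binning groups assembled contigs into draft genomes (MAGs) by
coverage covariation across samples and by k-mer composition. Both signals
are noisy, so bins routinely carry misassigned contigs: fragments of
co-abundant organisms, phage and plasmid sequence that mimics the host's
abundance profile, and compositional strays. Single-copy marker-gene
audits (the standard completeness/contamination estimate) cannot see most
of this, in particular contamination from across domains. magrefine
implements a post-binning refinement stage built from three filters that
are independent of marker genes, plus the downstream bookkeeping a genome
catalog needs: quality gating, species dereplication, read-recruitment and
polymorphism statistics, and phylogenetic-diversity accounting.

# The three decontamination filters

## Taxonomic filter

Every contig and every bin gets a ranked lineage from a contig classifier
(CAT/BAT-style). Lineages are first **trimmed** from the low end while the
last node is (A) suggestive — a low-support assignment, starred in the
classifier output; (B) at or below species rank; or (C) ambiguous —
"environmental samples" or a name starting with "unclassified". Trimming
is idempotent by construction.

A contig is **consistent** with its bin when the lowest common ancestor of
the two trimmed lineages equals one of them — equivalently, when one
lineage is a prefix of the other. For a bin classified
`class C1; order O1; family F1`, a contig classified `class C1; order O1`
or `...; family F1; genus G1` is consistent; `...; family F2` or
`class C1; order O2` is not. Inconsistent contigs are removed.

Two decisions were genuinely open:

* **Unclassified contigs are kept.** An empty trimmed lineage is a prefix
  of everything. Removing unclassifiable contigs would gut genomes of
  novel lineages, which is exactly what a marine catalog is after; the
  filter targets demonstrated *inconsistency* only.
* **The bin lineage is not re-derived after removals.** The filter runs
  once, non-iteratively; iterating would couple the filters and make the
  removal set order-dependent.

Bins whose lineage carries an internal-standard species
(*Thermus thermophilus*, *Blautia producta*; configurable) can be dropped
wholesale with `isInternalStandard()` before refinement.

## Mobile-element filter

Viral and plasmid contigs often share both coverage and composition with
their host, so they evade the other two filters. Three evidence routes are
evaluated independently and OR-ed:

1. **Terminal redundancy.** A contig assembled from a circular template
   repeats its start at its end. `detectTerminalRedundancy()` reports the
   longest prefix/suffix match of at least 50 bp (exact by default; a
   mismatch-tolerant mode takes a rate, e.g. 0.05). Candidate overlap
   lengths are located by seed matching, then verified over the full
   overlap, which keeps the scan linear in practice; an exhaustive scan is
   kept in the test suite as the oracle.
2. **Viral prediction.** Whole-contig predictions (categories 1–3) are
   viral outright. Provirus predictions (categories 4–6) count only when
   the viral region covers at least half the contig — an integrated
   provirus on a mostly-host contig should not remove the host sequence.
   The predictor operates on contigs of at least 3 kb, so shorter contigs
   never fire this route.
3. **terL scan.** For short contigs (1–10 kb, inclusive) where the
   predictor is weak, a hit against the terminase large subunit — a
   hallmark gene of tailed phages — flags the contig. A hit counts when
   the HMM e-value is strictly below 1e-10, the best domain is one of the
   seven pfam terL families, and the HHsearch probability is strictly
   above 97%.

Boundary semantics follow the printed thresholds: the e-value and
probability cuts are strict, the 50% viral-region fraction and the 1/10 kb
length range are inclusive. Routes are independent; a circular 12 kb
contig is flagged by route 1 regardless of the others.

## Outlier filter

Within one bin, contig composition and coverage should be homogeneous.
Two separate PCAs are run per bin:

* **composition** — each contig is a vector of canonical tetranucleotide
  frequencies. The 256 4-mers are pooled with their reverse complements
  into 136 strand-symmetric classes (the standard representation in
  binning practice), windows containing non-ACGT letters are skipped, and
  the vector is normalized to sum to 1;
* **coverage** — the bin's slice of the per-sample coverage profile, each
  sample column divided by its column sum over the bin, so samples of
  different depth are commensurate. Column-sum normalization was chosen
  for its scale-invariance; max- or z-normalization are exposed only
  through `normalizeCoverage()` replacements.

For each matrix the rows are centered (no variance scaling, the default
behaviour of `prcomp`), projected on the first principal axis, and the
scores standardized to mean 0 and population (n-denominator) standard
deviation 1. A contig is removed when its score lies strictly outside
±2.5 in either analysis. The two feature spaces are deliberately kept in
separate PCAs rather than concatenated: their units are incomparable and a
joint decomposition would be dominated by whichever block varies more.
Degenerate inputs yield *no* scores rather than zeros: a single-contig
bin, a constant matrix, or a missing coverage profile simply cannot flag.
Note a 2-contig bin standardizes to |z| = 1 for both members, so it can
never flag either — the filter needs a population to define an outlier.

## Orchestration and requalification

`refineBin()` runs all three filters on the *original* bin — no filter
sees another's removals, so per-filter flag sets are order-invariant — and
removes the union. A contig flagged twice is attributed to both filters in
the report but removed once. Survivor sequences are byte-identical and
keep input order. Completeness/contamination of the refined bin are then
re-estimated externally (marker-gene estimation is deliberately out of
scope) and fed to `requalify()`: a bin is discarded when its new quality
score QS = completeness − 5 × contamination falls strictly below 50;
QS ≥ 50 keeps, and QS may legitimately rise when contamination is removed.

# Quality scores, tiers, dereplication

`qualityScore()`, `isQualified()` (inclusive at 50, no rounding applied)
and `representativeScore()` (QS + ln N50, N50 in bp) are the scoring
primitives. MIMAG tiers use the standard's thresholds — high: completeness
> 90, contamination < 5, all three rRNAs, ≥ 18 unique tRNAs; medium:
completeness ≥ 50, contamination < 10 — exposed as arguments since the
tiers are a community convention, not a fitted quantity.

Species-level clustering consumes a pairwise table of ANI and aligned
fraction and applies **greedy centroid clustering**: genomes sorted by
representative score (ties: smallest id), each unassigned genome founds a
cluster and absorbs its unassigned neighbours at ANI ≥ 95% and AF ≥ 30%
(inclusive). This replaces the average-linkage machinery of dRep-style
tools with a deterministic rule; borderline chains can split differently
than average linkage would, which is accepted and documented rather than
hidden — no equivalence with any particular tool is claimed. Two-round
dereplication first clusters within each metagenome division, pools the
round-1 representatives, and re-clusters the pool; round 2 reuses the same
edge table restricted to the pool rather than recomputing comparisons.
`estimateAni()` provides a Mash-style k-mer approximation
(ani = 100(1 + ln(2J/(1+J))/k), k = 16, canonical k-mers; AF by
containment of the smaller genome) for building edge tables when no
aligner output is at hand; it is an approximation and labelled as such.

# Population statistics

Alignment records carry read length, aligned length and edit distance
(from SAM: aligned length = read bases in M/=/X columns, edit distance =
NM tag; records lacking NM are rejected because identity would be
undefined). Identity is (aligned − NM)/aligned — the conventional
definition, adopted because the upstream tooling this mirrors does not
document its exact formula. The recruitment filter keeps records at
≥ 95% identity, ≥ 80 bp and ≥ 80% aligned fraction of the read, all
inclusive, and `recruitmentFraction()` counts *distinct* read ids with at
least one surviving alignment. SNP sites are called on sites of depth
≥ 10 where the dominant base is ≤ 0.8 of reads (both inclusive);
heterogeneity is 1000 × SNPs/tested sites, and is NA — not 0 — when no
site is tested. All depth-qualified sites count as tested; no reference
positions are excluded.

# The synthetic-data generator

`makeGenome()` draws order-3 Markov DNA whose per-context transition
probabilities jitter around a target GC (realized GC within ±0.02, with
one deterministic correction pass). `makeBin()` fragments a host genome
into 3–5 kb contigs — a realistic size range for marine MAG assemblies
that also keeps every contig inside both the viral predictor's ≥ 3 kb
range and the terL scan's 1–10 kb window — and plants the three
contamination modes with known truth: a host-derived contig with a
conflicting family label (taxonomic), a contig with a written-in 60 bp
terminal repeat or attached viral/terL evidence cycling across the four
evidence routes (mobile), and a contig drawn from a GC-shifted composition
model whose coverage is also scaled ×8 in one sample (outlier). Host
contigs get consistent lineages — full paths, prefixes, genus extensions,
starred or species-bearing tails that trimming removes, some unclassified
— host-like coverage (per-sample means 5–30×, 5% log-normal noise over 4
samples), and no evidence rows.

The **easy** preset (GC shift 0.15, coverage ×8) is the validation regime:
30 bins of 24 contigs, 3 plants each, where full recovery with zero false
flags is expected and asserted. The **hard** preset (GC shift 0.04,
coverage ×2) exists for sensitivity exploration and carries no guarantee.
What the generator does *not* emulate — sequencing error, chimeric
contigs, strain mixtures, correlated coverage between contaminant and
host, ragged contig-length distributions — bounds what passing tests
mean: they demonstrate the machinery is correct and recovers strongly
divergent contaminants, not that real-data sensitivity reaches any
particular level. Pileups are simulated with Poisson depth and planted
minor-allele fractions in [0.25, 0.5]; alignment sets are constructed so
that exactly ⌊n·f⌋ reads pass and every failing record fails exactly one
criterion. All generation runs under `withSeed()`, which restores the
caller's RNG state; fixture sets derive per-bin seeds deterministically
from a master seed.

# Phylogenetic-diversity expansion

Trees arrive as newick with branch lengths (tree inference is out of
scope). `midpointRoot()` places the root halfway along the longest
leaf-to-leaf path, conserving total branch length; a tree of all-zero
branch lengths has no defined midpoint and is returned as-is. Given a
partition of the leaves into "new" genomes and the rest,
`pdCategories()` assigns each edge to category 1 when *every* leaf below
it is new (the clade-exclusive reading; an alternative path-to-root
attribution would credit shared backbone edges and was rejected as
overcounting), else category 2. If the midpoint splits an edge, each half
follows the same descendant rule, so with mixed children both halves land
in category 2. Zero-length edges carry zero weight and need no special
casing. The expansion percentage is 100 × category-1 / category-2 length.

# Numerical choices and problem sizes

Sanity suites run at sizes chosen to exercise the mathematics, not to
impress: oracle equivalence uses 1,000 random lineage pairs against an
explicit taxonomy-tree LCA, 100 random 10×5 matrices against a direct
eigendecomposition (agreement well below 1e-8), and 200 planted sequences
against an exhaustive prefix/suffix scan; branch-length conservation is
checked on 100 random 10-leaf trees at 1e-9; heterogeneity is recovered on
a 100 kb pileup at SNP rate 0.004 within three binomial standard
deviations of 4/kb. Catalog accounting is pure arithmetic on published
run totals shipped with the package (`marineCatalogCounts()`); one of the
printed figures (80.1% still-representative) is the sum of two
independently rounded percentages and differs from the exact ratio
(80.05%) in the first decimal, which the tests acknowledge with a
relative tolerance.

# Known limitations

* Completeness re-estimation after refinement is external; `requalify()`
  trusts the supplied assessment.
* The greedy centroid clustering is not average linkage; cluster counts on
  borderline chains may differ from dRep-style tools.
* `estimateAni()` is a k-mer sketch approximation, unsuitable below ~90%
  identity where the Jaccard signal saturates.
* The SAM reader covers the subset the statistics need (CIGAR + NM); it is
  not a general-purpose SAM parser.
* Coordinates are 1-based inclusive everywhere, matching pileup
  convention.
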