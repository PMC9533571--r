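---
title: "Methods: T-DNA insertion-site mapping from genome-walking amplicon reads"
author: "tdnawalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T-DNA insertion-site mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models, parameters and design choices behind
`tdnawalk`, in the spirit of a methods section: what each stage assumes,
why the defaults are what they are, and what the simulation-based tests
do and do not demonstrate.

## 1. The assay and its geometry

A T-DNA insertion creates two junctions between vector sequence and plant
DNA, one at each border repeat (left border, LB; right border, RB).
Genome-walking PCR amplifies outward from a nested border primer, across
the junction, to the nearest occurrence of a palindromic hexamer that
anchors the 3' end of a semi-random walking primer. After adapter
attachment, paired-end 2×150 bp sequencing reads the amplicon from both
ends: read 2 starts at the transgene end (it carries border sequence and
then crosses into plant DNA), read 1 at the walking end (plant DNA,
reading back toward the junction).

This geometry fixes the strand relationships the site caller exploits.
Take an insertion whose RB faces the upstream (lower-coordinate) flank —
the configuration we label **RB-LB**, reading the reference left to
right. The RB-library border primer extends leftward into the upstream
flank, so its synthesis product is the reverse complement of the
reference: read-2 fragments from the RB library match the minus strand,
read-1 fragments the plus strand. In the LB library the extension runs
rightward into the downstream flank and the pattern mirrors: read 1
minus, read 2 plus. The **LB-RB** configuration inverts all four signs.
`infer_orientation()` lets every informative hit vote under this rule and
reports a call only when at least 80% of votes agree (the quorum is a
package choice; the worked description the rule derives from presents a
single consistent pattern, so any sizeable minority of opposing votes
indicates chimeric amplicons or a mixed cluster and is better reported as
`undetermined`). With both borders simulated, junction coordinate order
(RB flank upstream of LB flank for RB-LB) follows from the same
geometry; the strand votes alone are sufficient and are what the
implementation uses.

Read-2 fragments begin exactly at the junction, which is why
`estimate_junction()` takes the median of their junction-proximal subject
coordinates; read-1 fragments start at the walking motif, up to ~1 kb
away, and are used only as a fallback.

## 2. Vector trimming

Read 2 is aligned to the vector reference (one sequence per construct)
with an affine-gap Smith–Waterman (match +2, mismatch −3, gap open −5,
gap extend −2; a gap of length *g* costs `open + g·extend`). A pair is
retained when the best alignment scores ≥ 40 **and** beats the best
alternative placement — any other construct, the opposite strand, or the
same sequence with the winning interval masked — by ≥ 10. This
score-and-margin filter plays the role a mapping-quality cutoff plays in
read mappers, but is aligner-independent and explicit. Reads shorter than
16 bp are rejected outright.

The genomic fragment is the read terminus on the **border-distal** side:
the end that, given the alignment's position and strand relative to the
border coordinate on the vector, points away from the T-DNA into plant
DNA. Computing the side from the geometry (rather than hard-coding
5'-clip for LB and 3'-clip for RB) makes vectors recorded in either
orientation behave correctly; the per-border hard-coded rule is the
special case of a vector written RB→LB. Fragments shorter than 20 bp are
discarded — shorter clips are dominated by chance matches — and read 1 is
kept whole when it has no credible vector alignment, since amplicons
longer than ~220 bp put read 1 entirely in plant DNA. Duplicate fragment
sequences are collapsed to their first representative without
re-orientation, matching a read-level unique filter.

Adapter read-through (amplicons whose insert is shorter than the read) is
trimmed by suffix–prefix overlap (≥ 8 bp, ≤ 10% mismatches); a fully
contained adapter followed by filler bases is removed together with
everything after it, since downstream of the adapter nothing originates
from the template.

## 3. Genome search and e-values

Fragments are matched against the reference with a seed-and-extend
search: exact 11-mers are looked up in a hash index of the forward
strand (the fragment's reverse complement covers the minus strand),
seeds are grouped by diagonal (±15) and each group is extended by banded
Smith–Waterman in a window padded 25 bp around the seeds. A group must
contain at least two seed words before it is extended (`min_seeds = 2`) —
the classical two-hit heuristic; isolated 11-mer collisions occur by
chance about once per 4 Mb per word and essentially never recur on one
diagonal, while any ≥95%-identity alignment of usable length contains
multiple exact words. Setting `min_seeds = 1` restores exhaustive
extension, which the test suite uses when checking agreement with a full
dynamic-programming oracle.

Significance follows the standard extreme-value model for ungapped
nucleotide statistics, `E = K·m'·n'·exp(−λS)`: λ solves the
score-generating equation for the uniform-composition scheme (λ =
0.6337 for +2/−3), K = 0.408 is the published constant for this scheme,
and the effective lengths subtract the expected chance-alignment length
`ln(K·m·n)/H` from query and database. Hits are reported when identity ≥
95% and E ≤ 1e-10; both thresholds are the pipeline's canonical search
settings and are exposed as parameters. No best-hit cap is applied: in an
allopolyploid, the homeologous copies of the true locus produce doublet
or triplet hits that carry information downstream.

## 4. Site calling

Hits are chained per chromosome by single linkage on start positions with
a 1 kb gap. The 1 kb radius is stated for left/right-border pairing; the
within-border chaining radius is not separately specified, and using the
same value keeps pairing and chaining consistent (two hotspots are
separated only if no two hits bridge them within 1 kb). Clustering is
idempotent, and adjacent hotspots with complementary borders within 1 kb
are merged into one candidate site.

Ranking is a deterministic lexicographic order on the evidence hierarchy:
both-border support first, then the count of remaining true flags
(multi-library, strong statistics — e < 1e-30 or identity > 99% —,
longest supporting fragment ≥ 60 bp, cross-line uniqueness), then total
read support, then best e-value, then coordinates. The source method
describes a weighted prioritisation without numeric weights; a strict
lexicographic order reproduces the stated hierarchy and is reproducible.
Whether the pooled library counts toward "more than one library" is a
configuration switch (`count_pooled`, default `TRUE`).

**Homeolog resolution.** Candidate sites sharing ≥ 50% of their
supporting fragments (transitively) form a homeolog group of typically
1–3 members. A group resolves to the member whose mean hit identity
exceeds every other member's by > 0.5 percentage points, provided it is
not outnumbered in supporting reads (`count_ratio = 1`). The count
condition is deliberately a guard rather than a dominance requirement:
under uniform homeolog divergence, nearly every fragment long enough to
pass the e-value ceiling also matches the homeologous copies above the
95% identity floor, so read counts at the true locus and its homeologs
are near-equal even when identity separates them decisively — demanding
a 2× count advantage would force ties exactly where the identity
evidence is clearest. With undiverged homeologs all statistics coincide
and the group is reported as a tie of all members, each kept as a valid
candidate. One site per group (the resolved locus, or the best-ranked tie
member) is flagged primary and primaries carry a dense re-ranking, giving
one candidate per putative insertion.

Verification-primer windows are placed 250–500 bp on either side of the
estimated junction and clipped at chromosome ends; windows never contain
construct sequence (a cross-module simulator check).

## 5. Zygosity calculus

The two-PCR design makes the genotype a pure function of two binary
outcomes: the T-DNA-anchored PCR A is positive iff a junction allele is
present, the T-DNA-flanking PCR B is positive iff an insertion-free
allele is present (the intact T-DNA is too long to amplify across).
Hence `+/+` heterozygous, `+/−` homozygous, `−/+` wildtype/null
segregant, and `−/−` an assay failure reported as indeterminate and
excluded from ratios. Summaries print percentages on two denominators
because the field's reporting convention divides by the transgene-positive
carriers (het + hmz) even for the wildtype class; both that
`table_style` view and the all-typed-plants view are emitted. The
chi-square goodness-of-fit against het:hmz:null = 2:1:1 (selfed
hemizygote) is optional output; loci with p < 0.05 are flagged
non-Mendelian — the expected signature of, e.g., a homozygous-lethal
insertion, which shows zero homozygotes. Stacking analytics use the exact
product: the probability of full homozygosity at k independent
hemizygous loci is (1/4)^k (25% at k = 1, 6.25% at k = 2, 1.5625% at
k = 3); and after n linear-phase cycles border-containing template is
enriched (1 + n)-fold, 19× for the default 18 cycles.

## 6. The simulator: what it emulates, and what it does not

The generator reproduces the study conditions end to end: an
allopolyploid genome built from one random ancestral sequence per
chromosome, copied into `n_subgenomes` (default 3) with independent
substitutions at half the configured between-subgenome divergence
(default 0.02, i.e. ~98% homeolog identity — recently diverged, colinear
subgenomes without indels); T-DNA insertions with configurable
orientation and border truncation (truncation past the nested-primer
offset silences that border, emulating an undetectable insertion);
amplicons from the nested primer (70 bp from the border, within the
50–75 bp nested placement that lets read 2 span the junction) to every
in-range motif occurrence, size-selected to 150–1200 bp including 44 bp
of adapter tails; reads with constant Q30 qualities, substitution errors
(default 0.3%), exact PCR duplicates (5%), walking-primer mispriming
background (motif-to-motif genomic amplicons, 5% of pairs, with the
border primer absent — these are rejected by the vector filter, as in
wildtype control libraries), optional adapter dimers, and a pooled
library at a quarter depth alongside the per-primer libraries. T2
populations draw genotypes at 1/2:1/4:1/4 per locus (2/3:0:1/3 for
homozygous-lethal loci) and map them deterministically to PCR A/B
outcomes. All operations are bit-reproducible given the configuration
and seed.

Defaults not fixed by the assay description are single considered
choices: 100× amplicon depth (comfortably above the point where
deduplication saturates), 5% duplicate and background rates (modest
values; real libraries vary widely and wildtype controls can be
dominated by artefacts), and equal per-primer efficiency (real libraries
show strong per-primer skew; a skew can be emulated by scaling depths
per motif, but its realistic range is unknown).

What passing simulation tests **does not** show: performance on real
libraries with indels and structural read errors, chimeric or
concatemeric T-DNA integration, vector-backbone read-through,
integration-site sequence bias, or polymerase-specific mispriming
spectra — none of which the generator models. The homeolog model
(uniform divergence, no indels) is kinder to resolution than real
subgenomes with locally varying divergence; conversely it is harsher on
read-count separation, which motivated the resolution guard above.

`sample_detectable_positions()` plants insertions whose flanks both
carry an in-range walking motif. This mirrors the assay's own
limitation — an insertion without a nearby motif is invisible, and the
simulator reproduces that failure mode with a warning — while letting
recovery studies condition on detectability, as the validation studies
here do.

## 7. Numerical and I/O conventions

Coordinates are 0-based half-open internally and in BED output, 1-based
inclusive in TSV hit and site reports (with `sstart > send` on
minus-strand hits, the tabular-search convention); every report header
names its convention. Alignment tie-breaks are deterministic (forward
strand preferred between strands; earliest reference end within a
strand). Deduplication keeps first occurrences, ranking ties break on
coordinates, and re-running any pipeline stage on identical input is
byte-identical. Fragments shorter than the seed word are skipped with a
logged count. The studies in the test suite use 3×3 chromosomes × 0.5 Mb
at 100× depth for the end-to-end recovery scenario and two 25-insertion
single-subgenome runs for orientation accuracy; these sizes exercise
every code path (homeolog triplets, both borders, read-through, short
clips) while keeping a full validation run to a few minutes on one CPU.

## 8. Known limitations

* Seeding requires one exact 11-mer (two for extension by default): hits
  of marginal identity below ~40 bp can be missed relative to an
  exhaustive aligner; such fragments rarely clear the e-value ceiling
  anyway.
* K in the e-value formula is the published constant for the +2/−3
  scheme; other schemes require a user-supplied K.
* The orientation rule assumes the amplicon geometry above; libraries
  built with inverted adapter chemistry would need the read-1/read-2
  roles swapped.
* Homeolog resolution reports, not decides, biology: a tie is a
  statement that the data cannot separate the copies, and all members
  are retained for PCR verification.
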