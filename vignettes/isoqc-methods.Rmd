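---
title: "Methods: quality control and contamination detection for isolate sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and contamination detection for isolate sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoqc)
```

## The problem

Whole-genome sequencing of bacterial isolates is only as good as its weakest
sample. Two failure modes matter in routine surveillance labs: plain low
quality (too few bases, poor base calls, fragmented assemblies) and
contamination — foreign reads mixed into a nominally clonal isolate. The
second is the harder one: an assembly contaminated by a *different genus* is
easy to spot taxonomically, while contamination by a *closely related strain
of the same species* leaves the assembly looking normal and silently corrupts
SNP typing and outbreak analysis downstream.

isoqc computes a battery of QC metrics per sample, compares each against
species-specific threshold ranges, and aggregates them into a traffic-light
verdict (pass / warning / fail), written as a structured two-branch JSON
report. It also ships a synthetic-data generator and a benchmark harness that
measure, per metric, the sensitivity for intergenus and intragenus
contamination — separating what each metric can and cannot see.

## The metric suite

**Read level.** `compute_read_stats()` reports the Q30 base fraction
(proportion of bases with Phred quality ≥ 30) and the estimated coverage
depth `n_bases / L`, where `L` is the assembly length when the sample has an
assembly, else a supplied expected genome length. No trimming is performed;
metrics describe the input as given.

**Assembly level.** `assembly_stats()` filters contigs below 500 bp (a
configurable QUAST-style convention), then reports contig count, total
length, N50 (the largest contig length `l` such that contigs of length ≥ `l`
hold at least half of the assembly) and GC over unambiguous bases.
`map_contigs()` anchors contigs onto a reference by maximal runs of exact
reference-unique 31-mers, merged into blocks ≥ 200 bp — a deliberate
simplification of a genome aligner that is adequate for the low-divergence
case the QC setting needs. From the anchoring, `duplication_ratio()` is
*aligned assembly bases / reference bases covered ≥ 1×* — above 1 means
redundant, possibly mixed, assembly content — and `genome_fraction()` the
covered proportion of the reference.

**Reference selection.** `sketch_genome()` builds a bottom-s MinHash sketch
(default s = 1000, k = 21) over canonical k-mers, hashed with splitmix64 of
the 2-bit packing so sketches are identical across platforms and runs.
`select_reference()` estimates Jaccard similarity `j` on the merged bottom-s
sketch and converts it to the mash distance `d = -ln(2j/(1+j))/k`, with
`d = 1` for disjoint sketches and lexicographic tie-breaking.

**Taxonomy.** `build_kmer_index()` assigns every canonical 21-mer of a
labelled genome set to its lowest common ancestor: species-private k-mers to
the species, k-mers shared within a genus to the genus, k-mers crossing
genera are dropped as uninformative. `majority_fraction_reads()` classifies
each read by k-mer majority vote and reports the fraction of classified
reads assigned to the majority species (or genus);
`majority_fraction_contigs()` does the same per contig — best hit only,
weighted by contig length. The contig-level fraction deliberately
de-duplicates multi-copy plasmids: a 5 kb plasmid at copy number 10
contributes a third of all reads from a 100 kb genome but only ~5% of the
assembly, so a discordantly labelled plasmid depresses the read-level
fraction while the contig-level fraction stays high. The combined QC rule
(`combined_taxonomy_status()`) therefore fails a sample only when *both*
fractions fall below the purity threshold (default 0.95), and warns when
exactly one does. Fractions are computed over classified units only; the
unclassified share is reported separately.

**Typing.** `call_alleles()` matches scheme alleles as exact full-length
substrings on both strands, recording *all* matching alleles per locus; a
locus with two distinct alleles is the footprint of a mixed sample
(`duplicated_alleles()`, contaminated at ≥ 1 duplicated locus).
`sequence_type()` assigns a classical 7-gene ST only when every locus has
exactly one allele matching a profile row. `build_core_scheme()` constructs a
core-gene scheme alignment-free: a reference gene becomes a locus when it is
found exactly once, full-length at ≥ 90% ungapped identity (exact-k-mer
anchored placement), in ≥ 95% of genomes, and duplicated in at most 5%.
`allele_distance()` is the Hamming distance over loci non-missing in both
profiles, and `categorize_relatedness()` bins a contaminant as close (same
ST, distance 0), intermediate (1–6) or distant (≥ 7). The conventional bins
leave distance 1 unassigned; we assign it to intermediate, and read the
distant bound as ≥ 7. `core_gene_assessment()` is the completeness /
duplication check (the single-copy-orthologue analogue): percent of loci
found exactly once, count of duplicated loci, warning only when more than
one locus is duplicated — a single duplicated core gene is common enough in
clean data that flagging it would cost specificity.

**Contaminating SNVs.** The most sensitive intragenus signal re-implements
the read-level approach of ConFindr-style detectors: `bait_reads()` assigns
reads to the core-gene locus sharing most 31-mers; `pileup()` places each
baited read ungapped at its best exact-anchor offset and accumulates base
counts per site, dropping bases below Phred 20; `contaminating_snvs()` calls
a site a contaminating SNV when depth ≥ 10 and two bases are each supported
by ≥ 2 reads with the minor base at ≥ 5% of the depth; and
`contamination_call()` flags a sample at ≥ 3 SNV sites or any locus carrying
≥ 2 SNV sites (a multiallelic locus — the footprint of a second allele). The
base-quality filter is integral to the design: at 50× depth over a
100 × 1 kb scheme, unfiltered 1%-error data would produce hundreds of
chance sites with ≥ 3 identical error bases, destroying specificity, whereas
errors concentrate on low-quality bases and are removed by the Phred-20
filter. The contaminant fraction is estimated as the median minor-base
fraction over SNV sites (in percent): at mixing ratio r the contaminant
supports the minor base at close to r of the depth, so the median is an
essentially unbiased estimate for r < 0.5. Ungapped placement means
indel-bearing reads lose their anchors and are dropped — acceptable because
no metric here is indel-sensitive, and a documented limitation otherwise.

## Thresholds and the decision engine

`derive_species_thresholds()` turns a table of per-sample metric values into
species ranges: the empirical 5%/95% quantiles (linear interpolation, R
type 7 — fixed so derived thresholds are reproducible), for species with at
least 100 samples. `derive_genus_thresholds()` spans a genus as
[min of species lows, max of species highs]. Threshold lookup for a sample
walks species → genus → global; taxa without thresholds simply skip those
checks rather than failing them.

The verdict rule follows the two-tier criticality split: Q30 fraction,
coverage depth, assembly length, the *combined* taxonomy status and the SNV
contamination call are critical (a violation fails the sample); contig
count, N50, GC content, MLST allele duplication, core-gene completeness and
duplication, and the duplication ratio only warn. An optional warn band can
be nested inside any critical fail range; by default the two tiers collapse
(no warn band), since no principled narrower band exists a priori. The
bundled `default_thresholds()` table carries species ranges for four common
foodborne taxa plus the species-agnostic rules; the Q-score criterion is
encoded as a Q30 base fraction ≥ 0.80 (the published criterion is an average
Q ≥ 30; the Q30 fraction is the metric this package computes, and 0.80 is a
common Illumina acceptance value).

Reports have exactly two top-level branches: `pipeline` (raw per-module
results) and `sample` (run metadata, metric summary, per-metric statuses and
verdict). `validate_report()` checks this contract structurally and returns
violations rather than throwing; `filter_report()` prunes any branch absent
from a user-edited filter schema (identity schema = no-op; filtering is
idempotent), for sharing reduced reports. `run_batch()` processes a sample
sheet with per-sample failure tracking — an assembly that is empty after the
length filter becomes a recorded failure with its module and reason, not an
aborted batch — writes per-sample JSON (reused on reruns when input
checksums are unchanged), an aggregate TSV, and a static traffic-light HTML
table.

## The synthetic panel: what it emulates, and what it does not

All benchmark claims in this package are statements about the bundled
generator, whose defaults define the study conditions:

- **Genomes** (`simulate_genome()`): 200 kb i.i.d. sequence at a per-genus GC
  target (0.30/0.40/0.50/0.60 across the four panel genera — the GC span of
  common foodborne pathogens), with 100 designated core genes of 1 kb and an
  8 kb accessory segment. 200 kb is a deliberate desk-scale reduction of a
  ~2–5 Mb genome chosen to keep the full benchmark within minutes on one
  CPU; every contamination signal tested here scales with per-site depth and
  per-locus counts, not genome size.
- **Isolate variation** (`simulate_isolate()`): real isolates of one species
  differ mostly in accessory gene content, which is what spreads assembly
  length and GC within a species. An isolate resamples the accessory segment
  with log-normal length (median 8 kb, sdlog 0.5) and GC drawn around the
  species target (sd 0.05). Threshold ranges are derived from 100 such pure
  isolates per species; benchmark subjects are the species base genomes,
  which sit at the centre of those bands — mirroring how published
  benchmarks use curated strains against population-derived thresholds. A
  band derived from byte-identical replicates would be degenerate and flag
  meaningless 0.01-point GC shifts.
- **Relatives** (`simulate_relative()`): exactly `target_ad` core genes
  receive 3 substitutions each, so the allele distance to the subject is the
  target by construction — close (0), intermediate (4), distant (10) in the
  default panel.
- **Reads** (`simulate_reads()`): uniform positions and strands, plasmids at
  copy-number rate, substitution errors only at a mean rate of 1% with
  per-base qualities drawn from a Q40/Q10 mixture consistent with that rate.
  Reads are single-end: no in-scope metric is pair-aware, so mate structure
  would only duplicate the same base stream. ART-style error profiles,
  indels and quality-by-cycle structure are not modelled.
- **Pseudo-assembly** (`pseudo_assemble()`): a truth-aware stand-in for a de
  novo assembler, not an assembler. The subject is emitted as ~40 fragments
  (log-normal sizes) that tile the genome exactly, with breakpoints snapped
  out of core genes — at 50× a real assembler reconstructs single-copy core
  genes contiguously; breaks happen at repeats and coverage gaps.
  Contaminant sequence appears only when its effective depth
  (`coverage × ratio`) reaches 10×: a different-genus contaminant then adds
  its own fragments, while a same-genus contaminant adds only its divergent
  gene copies as extra short contigs (its backbone co-assembles with the
  subject). This encodes the mechanism by which low-ratio contamination is
  invisible at the assembly level, and it is why assembly-dependent
  benchmark cells are properties of this mechanism rather than statements
  about any particular assembler.

Because the panel genomes of different genera share no k-mers, the read
purity check is exactly as strong as the mixing arithmetic (a 10% intergenus
mixture gives fraction ≈ 0.90 < 0.95 — flagged), and intragenus mixtures —
whose reads all classify to the subject species — are exactly invisible to
it. The GC check cannot see an intermediate relative whose genome differs by
12 bases; the duplicated-MLST check cannot see a same-ST contaminant whose
alleles are identical. Conversely a distant (AD 10) relative plants 30
well-supported heterozygous sites in the core genes, far above the 3-SNV
cutoff at any tested ratio. These structurally forced outcomes are the
benchmark's acceptance anchors; sensitivity values for metrics in between
(contig count, duplication ratio, completeness) depend on the
pseudo-assembly mechanism and should be read qualitatively.

One known divergence from ConFindr, the tool this detector parallels: the SNV detector here
baits against a species-specific core scheme, so different-genus reads are
never baited and intergenus sensitivity of this one metric is ~0, whereas
ConFindr with the cross-genus rMLST scheme detects intergenus mixtures
(rMLST is copyright-restricted and not redistributed). Intergenus detection
in this package is the job of the read-level purity check, which is perfect
on the panel.

## Numerical choices and degenerate inputs

- Quantile type fixed to linear interpolation (R type 7); threshold bounds
  are inclusive on both sides.
- Sketch hashing is splitmix64 of the 2-bit packed canonical k-mer; index
  k-mers are capped at k ≤ 26 so packed values are exact in doubles.
- Classification ties collapse to the deepest common ancestor (tied species
  → unresolved at species rank; tied genera → unclassified).
- `select_reference()` breaks distance ties lexicographically; Jaccard 0 is
  reported at the maximum distance 1.
- Empty assemblies (after the length filter) are a reported status, not an
  exception — they drive the failed-sample logic.
- A zero-coverage anchoring (nothing maps) leaves the duplication ratio not
  assessed rather than dividing by zero; an all-unclassified read set leaves
  the purity not assessed.
- Coverage uses the assembly length as denominator when one exists (the only
  sample-intrinsic choice), else the configured expected genome length.

## Problem sizes used by the test suite

The packaged tests run the full benchmark conditions — four 200 kb genera,
50× coverage, ratios 10/20/30%, two replicates (72 intergenus and 24
intragenus samples per table row), thresholds from 100 pure isolates per
species — plus property suites on compact 30 kb / 10-gene genomes chosen so
the whole suite completes in minutes. All fixtures are generated in code at
run time; nothing binary ships with the package.
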