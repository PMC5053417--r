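---
title: "Detecting presence/absence variation between accession assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting presence/absence variation between accession assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two individuals of one species — here modelled on a pair of *Arabidopsis
thaliana* accessions — differ not only by SNPs and short InDels but by
larger structural variation: segments of 100 bp up to tens of kbp present
in one genome and absent at the orthologous position in the other
(presence/absence variation, PAV), and segments so diverged that short
reads from one accession cannot be mapped onto the other (highly diverged
regions, HDR). Short-read mapping alone cannot reveal sequence that is
missing from the reference being mapped against; with *de novo* assemblies
of both accessions, however, the comparison can be made reciprocally, and
every mapping gap can be interrogated on the other assembly.

pavscape implements that reciprocal procedure as a reusable, fully tested
pipeline, together with the surrounding analyses a genome-assembly
comparison needs: reciprocal-best-hit (RBH) protein synteny with outlier
typing and scaffold anchoring, k-mer genome-size estimation, read-depth
repeat quantification, and gene-space completeness filters.

## The detection procedure

One direction of the comparison maps accession A's reads onto accession
B's assembly:

1. **Mapping.** Reads are placed by seed-and-extend under the acceptance
   contract of the original analysis: at least 90% of the read aligned
   (`length_fraction = 0.9`) at no less than 95% identity over aligned
   columns (`similarity_fraction = 0.95`). Reads tied between identical
   loci are placed uniformly at random (`multi_mapper_policy = "random"`),
   so repeats receive their share of coverage and only true absence yields
   zero depth.
2. **Zero-coverage regions.** Maximal runs of depth exactly 0 of at least
   5 bp become ZCR records. Runs whose target sequence is more than 10%
   ambiguity characters (N and other IUPAC codes) are discarded — those
   are assembly gaps, not biology. Runs touching a sequence end are
   flagged and later labelled `unresolved` rather than classified.
3. **Flank anchoring.** For every ZCR of reportable size (>= 100 bp), the
   1 kbp flanks on both sides are aligned against the read-source assembly
   (best local alignment; match +1, mismatch −2, gap open 5, extend 2). If
   both flanks anchor on the same sequence, same strand, in the expected
   order, and the signed distance between the inner alignment ends is
   within tolerance, the region is absent from the read source: a **PAV**
   (equivalently, a deletion in the read-source accession and an insertion
   in the mapping target). The tolerance is 100 bp for ZCRs up to 1 kbp
   and 10% of the ZCR length above that. Everything that fails the
   adjacency test is an **HDR**.
4. **Mate-distance validation.** Proper read pairs spanning a PAV should
   show inner distances inflated by the missing sequence. A call is
   `supported` when the mean spanning-pair distance deviates from the
   global mean by more than 100 bp (two-sided), `indeterminate` below 3
   spanning pairs.
5. **Reciprocity.** The other direction (B's reads on A) finds the
   complementary event set; the reporting convention labels each PAV with
   the accession it is deleted from and inserted in.

### Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_zcr_len` | 5 | bp | smallest zero run recorded |
| `report_min_len` | 100 | bp | smallest ZCR classified (the SV floor) |
| `max_ambiguity` | 0.10 | fraction | ambiguity filter on ZCR sequence |
| `flank_len` | 1000 | bp | flank anchored in the counterpart |
| `pav_min_len` | 100 | bp | PAV/InDel boundary |
| `base_adjacency_tol` | 100 | bp | anchor adjacency tolerance (<= 1 kbp) |
| `rel_tol` | 0.10 | fraction | tolerance above 1 kbp |
| `pair_dev_cutoff` | 100 | bp | mate-distance deviation cutoff |
| `length_fraction` | 0.9 | fraction | mapping: aligned read fraction |
| `similarity_fraction` | 0.95 | fraction | mapping: identity over columns |

The adjacency tolerance below 1 kbp is not dictated by the source
procedure (which states only the >1 kbp rule); 100 bp is chosen to match
the stated purpose of the 100 bp PAV floor — compensating small
positioning inaccuracies of local alignment in diverged flanks.

## The mapper and its consequences

The mapper is deliberately small: exact 15-mer seeds at four offsets per
read and strand, ungapped verification on each candidate diagonal
(compiled code), and a banded gapped alignment (band 25) for reads that
fail ungapped. Reads are aligned end to end, so accepted placements always
have aligned fraction 1; partial (clipped) placements are never emitted.

Two consequences are worth understanding because they shape every
downstream number:

- **Identity counts gap columns.** A single InDel larger than ~5% of the
  read length (13 bp for a 250 nt read) pushes identity below 0.95, so
  reads spanning it are unmapped. An isolated InDel of that size only
  uncovers a region of its own length (< 100 bp, below the reporting
  floor), but *clusters* of such InDels within one read length of each
  other produce genuine >= 100 bp dead zones. These classify as PAV with a
  small inner distance — they are real detections of real variation, and
  the benchmark accounts for them explicitly.
- **Read-overhang margins.** A read may overhang a true breakpoint by
  ~16 bp (the mismatch budget at 75% mismatch density in the scrambled
  tail), so a ZCR is typically ~30 bp shorter than the implanted event.
  Implanted events of ~100-130 bp therefore shrink below the 100 bp
  reporting floor and are missed: a detection limit of the method at its
  own floor, visible in the benchmark as per-seed recall around
  0.93-0.98 rather than 1.0.

The band of 25 covers the cumulative diagonal drift of the several small
InDels a read can legally span; the 0.95 identity bound, not the band, is
what rejects larger InDels.

## The synthetic accession pair

`generate_ancestor()` + `derive_accession()` produce the statistical
structure the detection assumes, with every variant recorded in a truth
registry whose replay (`apply_registry()`) reproduces the derived genome
exactly — string equality, asserted in the tests.

- Background SNPs at 1/292 bp and small InDels (1-20 bp) at 1/1500 bp:
  the SNP rate is the published genome-wide rate for this accession pair;
  the InDel rate follows from the published all-variant (1/244) vs
  SNP-only (1/292) frequencies.
- Large events: counts are configured (the standard recovery experiment
  implants 20 deletions and 20 insertions), lengths log-uniform over
  100 bp-25.6 kbp by default so every doubling reporting bin is
  exercised; the recovery benchmark restricts to 100 bp-10 kbp.
- HDR blocks are modelled as contiguous segments with a 10x elevated
  SNP/InDel density — divergence, not novel sequence. No published length
  distribution exists for real HDRs; the log-uniform 100 bp-10 kbp default
  is a modelling choice.
- Tandem arrays (e.g. a 180 bp centromere-like unit, a 10 kbp rDNA-like
  unit) are embedded at recorded positions; a collapsed-duplicate locus
  (two identical gene copies in one accession, one in the other) feeds the
  >= 2x genic-coverage flag.
- Placement isolation: large events keep >= 2 kbp apart and away from
  arrays and sequence ends, so each event's 1 kbp flanks are clean test
  cases. Background small InDels are additionally excluded within 300 bp
  (one read span) of large-event footprints — a >= 14 bp InDel that close
  merges its own mapping dead zone with the event's ZCR and corrupts the
  adjacency distance. Background SNPs are *not* excluded from flanks;
  anchoring is supposed to tolerate them.

Reads: fragment lengths are Normal(insert, sd) truncated at twice the
read length — "insert" is the outer fragment length, as in the library
protocols this emulates — with uniform fragment starts, inward-facing
pairs for paired-end and outward for mate-pair layout, and i.i.d.
substitution errors. What the simulator deliberately omits: quality-score
models, PCR duplicates, chimeric reads, coverage biases, and organelle or
contaminant sequence. Passing the recovery benchmark therefore shows the
*procedure* is correct under its stated assumptions, not that real
libraries are this clean.

## The recovery benchmark

`run_benchmark()` is the package's standard experiment: a 1 Mbp ancestor,
20 + 20 implanted events, 30x error-free 2 x 250 nt paired-end reads with
a 700 bp insert, run reciprocally and scored against the registry. A truth
event counts as recovered when a PAV call of the right direction overlaps
it; a call counts as *false* only when no truth variation of any kind lies
within a read span of it (clustered-InDel dead zones are matched to the
truth InDels that cause them). Typical results: recall 0.93-0.98,
zero false calls, all direction labels correct, and every PAV call
supported by the mate-distance check. Problem sizes throughout the test
suite (40 kbp-1 Mbp genomes, 20-30x) were chosen as the smallest scales at
which every mechanism — multi-mapping, adjacency tolerance switching,
mate-distance support — is actually exercised.

## RBH synteny

Protein scoring is Smith-Waterman with BLOSUM62 (gap open 11, extend 1).
The e-value surrogate uses the Karlin-Altschul form
E = m·n·2^(−(λS − ln K)/ln 2) with the ungapped BLOSUM62 constants
λ = 0.267, K = 0.041: only the decision against the 0.001 cutoff is meant
to be calibrated, not absolute e-values. Best hits tie-break by lower
e-value then lexicographic subject id, so reruns are deterministic. RBH
ranks are 0-based positions in each assembly's position-sorted RBH gene
list (unplaced scaffolds ordered last).

Dot-plot outliers are detected against the median rank of the five
nearest rank-neighbours with a 20-rank deviation threshold. Both knobs are
configurable because the original analysis identified outliers visually;
any reasonable local-median rule finds the same relocations, but absolute
outlier counts are rule-dependent and are not comparable across
implementations. Outlier typing follows the published distinction:
**random** when either member has two or more hits within 95% of its best
score (the pairing was arbitrary among near-identical copies), **real**
otherwise.

Scaffold split hints flag junctions between consecutive RBH genes whose
counterpart positions jump chromosomes or more than the rank threshold,
requiring two internally consistent genes on each side so a single stray
outlier cannot break a scaffold. Anchoring assigns each scaffold the
chromosome holding the weighted majority (>= 60%, else unplaced) of its
evidence, orients by the sign of the Spearman correlation between
scaffold and chromosome coordinates, orders by median counterpart
coordinate, and emits AGP v2.0 with 100 bp gaps.

## Genome metrics

**k-mer genome size.** Canonical 25-mers are counted from reads; the error
tail is separated at the first local minimum of the 3-bin moving-average
smoothed histogram; genome size is the total k-mer observations above the
boundary divided by the coverage-peak depth. One numerical choice
matters: after locating the modal multiplicity, the peak depth is refined
by a count-weighted centroid over mode ± 2. The true k-mer depth is not an
integer (it is coverage scaled by (L−k+1)/L), and the raw integer mode
makes the estimate jump by a full 1/mode (≈ 4% at 27x) whenever sampling
noise shifts the argmax by one bin; the centroid removes that
discontinuity. On 30x error-free reads of a 100 kbp genome the estimate
is within 2% of truth. The estimator includes all multiplicities above
the error boundary (the high-multiplicity repeat tail is genome content);
heterozygosity-aware mixture modelling is out of scope — the data this
emulates come from a selfing accession.

**Repeat copy number.** copies = mean depth over the repeat reference x
reference length / unit length / single-copy depth. The reference is
three adjacent unit copies and the mean is taken over the whole
reference: by conservation, every array-derived read is placed somewhere
on it, so the whole-reference mean is insensitive to how the random
multi-mapper distributes reads among the copies (the per-copy profile is
not flat), and the 3-copy layout lets unit-junction-spanning reads place
full length. At published scale the same arithmetic reproduces ~400 rDNA
units ≈ 4 Mbp and ~60,000 centromeric 180 bp units ≈ 11 Mbp.

**Composition.** genome-size estimate − assembly = unassembled; minus the
rDNA total = centromeric, split equally over five centromeres. With the
published inputs (146 Mbp, 117 Mbp, 4 Mbp) this yields 29, 25 and 5 Mbp.
The source text quotes ~4.5 Mbp per centromere where the stated formula
gives 25/5 = 5; the implementation follows the formula and notes the
discrepancy (possibly a telomere allowance).

**Completeness filters.** Exons (> 50 bp) count as present when their
best hit reaches 50% of their self-score, under a greedy
one-hit-per-region rule (highest score first; claimed regions close to
overlapping later hits — the region-resolution rule is otherwise
undefined). ESTs count as mapped at >= 95% query coverage and >= 90%
identity. Scaffold ends (terminal 2 kbp of scaffolds > 4 kbp) are checked
for transposable-element overlap at their anchored positions.

## Degenerate inputs and tie-breaks

- Empty sequence sets, empty histograms, single-multiplicity histograms,
  zero proper pairs, and genes of zero length raise errors naming the
  problem rather than returning silent defaults.
- All tie-breaks are deterministic (score, then e-value, then
  lexicographic id, then coordinate); the only randomness is the seeded
  multi-mapper placement, and every seed is recorded in outputs.
- Sequence-edge ZCRs and clipped flanks are `unresolved`, never HDR:
  events at assembly ends are undecidable by flank adjacency.

## Known limitations

- The mapper is glocal (whole-read); split and clipped alignments are out
  of scope, so breakpoints are resolved only to the read-overhang margin
  (~16 bp at default settings) and events within ~30 bp of the reporting
  floor can be missed.
- HDR calling is operational (mapping failure + failed adjacency), not a
  divergence estimate; moderately diverged blocks that still accept reads
  are invisible.
- CNV is not called (only the >= 2x genic-coverage flag is provided);
  absolute dot-plot outlier counts are rule-dependent; e-values are
  surrogates.
- Coordinates are resolved per assembly; no attempt is made to build a
  base-level whole-genome alignment.
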