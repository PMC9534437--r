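---
title: "Genotyping a complex paralogous locus from long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a complex paralogous locus from long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pharmacogenes like *CYP2D6* resist standard genotyping: the gene sits next
to the ~94%-identical pseudogene *CYP2D7*, carries over a hundred named
star-alleles defined by combinations of SNVs, small indels, whole-gene
deletions and duplications, and frequently forms *CYP2D6–CYP2D7* hybrid
genes. Short reads cannot be mapped confidently inside the paralog pair,
and callers that handle small variants ignore the large structural
events (and vice versa), so the two classes of variation are never
resolved jointly on the same allele.

`locustar` implements a comprehensive genotyping pipeline for such loci
from Cas9-enriched nanopore-style long reads. It takes a ~28 kb locus
reference with two annotated gene copies, a FASTQ of long reads, and a
PharmVar-style star-allele definition table, and produces: phased
per-allele consensus sequences with a per-base confidence track, large
structural variants with read support, per-copy small variants with
quality scores, the gene/hybrid structure of each allele, and a
star-allele diplotype string such as `*5/*4+*68`.

## Pipeline model

The pipeline mirrors the four-panel workflow of comprehensive long-read
genotypers for this locus class:

1. **Map and filter.** Reads are aligned to the locus with minimap2
   (`map-ont`, single thread, supplementary alignments and soft clips
   preserved). Reads are kept when their mean basecall quality exceeds 8
   (the conventional nanopore pass threshold, strict inequality) and
   their primary alignment overlaps the target and covers at least 50%
   of the read.
2. **Small variants and allele split.** A transparent pileup caller
   genotypes every column by maximum likelihood over hom-ref / het /
   hom-alt with a symmetric per-base error rate ε (default 0.1,
   ONT-like; the SNV model spreads ε over the three alternative bases,
   indel events are binary). Candidate sites need at least two
   supporting reads and a 15% allele fraction before the likelihood is
   even evaluated — below that the hom-ref model always wins at any
   plausible ε, so the cut only saves time. Heterozygous SNVs then
   drive a greedy margin-based read partition: starting from the read
   covering the most het sites, reads are assigned to the haplotype
   they match at more het sites, and the haplotype consensus is refined
   each pass until a fixed point (at most 10 passes). Zero-margin reads
   stay unassigned; they are recovered later against the allele
   consensus sequences, which is also why ties are *not* broken
   randomly. Het sites sharing no read form separate phase blocks.
3. **Structural variants and adjusted references.** All junction
   evidence is reduced to pairs of reference coordinates: soft clips of
   at least 200 bp are cut in silico and remapped to the locus;
   supplementary (split) alignments and ≥200 bp deletion gap operations
   are converted into equivalent junction pairs directly, so either
   aligner behaviour feeds one code path. When split segments overlap
   in read space (junction microhomology), the double-counted bases are
   trimmed off the left anchor — otherwise every supporting read would
   inflate the event by the microhomology length. Junctions are
   clustered per allele by single linkage with a 20 bp tolerance on
   both coordinates; the cluster position is the median and clusters
   with fewer than three supporting reads are discarded. A forward
   junction is a deletion, a backward junction a tandem duplication,
   and a duplication spanning parts of both genes a hybrid insertion.
   Each allele then gets an adjusted reference with its events spliced
   in (duplications inserted in tandem 3′ of their source) and a
   segment map recording provenance for lift-over.
4. **Consensus, gene identification, star-alleles.** Each allele's
   reads are realigned to its adjusted reference for a first majority
   consensus; all on-target reads are then re-assigned to the
   first-round consensus they align to with a score margin of at least
   10 (~2 matches) — ambiguous reads are removed. The cleaned
   assignment supersedes the initial phasing for junction evidence:
   structural variants are re-detected per allele from the re-assigned
   reads, the adjusted references are rebuilt, and the final consensus
   is produced against them with the same column logic. This second
   detection pass is what makes the pipeline robust to initial
   misphasing — when reads of a structural allele are first scattered
   across both alleles, their junction clusters can land on the wrong
   allele and be shadowed by a higher-support event until the
   consensus-based re-assignment separates the reads. The two gene references are
   mapped to each final consensus; every ≥90%-identity hit interval is
   a candidate gene copy (zero copies of the target gene plus a
   covering deletion event ⇒ a deletion allele). Within each copy an
   exact two-state dynamic program over *diagnostic positions* (columns
   where exactly one source gene mismatches) assigns every stretch to
   the source with the fewest mismatches, with a switch penalty of 3
   diagnostic mismatches; hybrids are the concatenation of the
   assigned fragments. Per-copy variants are the assigned source's
   remaining mismatches, with quality `Q = −10·log10(1 − p)` (capped
   at 60) from the consensus probability track. Finally each copy is
   matched to the star-allele table: structural labels first (deletion
   alleles by the event, hybrids by whether the definition's gene-local
   switch region contains the detected switch), sequence-defined
   alleles by Jaccard similarity over normalized variant sets, ties
   broken by fewer missing defining variants, then fewer extras, then
   the lowest star number. Extra and missing variants are reported
   verbatim — star nomenclature is intrinsically incomplete and the
   extras often carry the sub-allele signal.

### Consensus details

The consensus is a deliberate replacement of neural polishing by a
transparent, oracle-checkable majority vote: per reference column the
majority base among `{A, C, G, T, gap}` wins (ties favour the
reference), insertions are accepted when carried by more than half of
the covering reads, and the emitted probability is the
Laplace-smoothed majority fraction `(votes + 1) / (depth + 2)` — a
depth-0 column therefore emits the reference base at the floor of 0.5
and is flagged. Homopolymer runs of length ≥ 4 are the dominant
nanopore error mode and get special treatment: instead of independent
column votes, each fully-covering read votes for an observed *run
length* (aligned matching bases plus adjacent same-base insertions) and
the modal length is emitted, with ties resolved toward the reference
length. With error-free reads every vote is unanimous, which gives the
zero-noise identity property, and a further round with unchanged reads
is a fixed point.

### Reliability

A mean depth of 16X per gene copy per allele is the reliability limit
for small-variant calling: below it, copies are flagged
`low_confidence` but calls are still emitted, since correct star-allele
assignments are routinely achieved below the threshold. The
depth-reliability curve (`depth_reliability_curve()`) makes the
false-positive behaviour below the limit measurable on any dataset: it
re-runs calling on subsampled read sets and counts calls absent from
the full-depth baseline.

## The synthetic-data generator

Every stage is testable at desk scale because the package ships a
generator that emulates the study system:

* **Locus**: 28,206 bp with two 4,382 bp gene copies at 94% identity
  (`synthetic_locus()`), the CYP2D6/CYP2D7 geometry. Gene 2 is a
  mutated copy of gene 1, so diagnostic positions arise at ~6% density
  exactly as in the real paralog pair.
* **Structural events** (`synthetic_events()`): a 12,152 bp whole-gene
  deletion and a 13,680 bp tandem hybrid duplication whose
  locus-relative breakpoints mirror the well-characterized HG01190 *5
  and *4+*68 alleles; breakpoints fall in unique flanking sequence, as
  they do at the real locus.
* **Star-allele table** (`synthetic_star_table()`): *1 (reference), *2
  and *4 (SNV sets), *3 (frameshift deletion), *5 (gene deletion), and
  the hybrids *68 (switch region 600–1000, simulated as a
  duplication-insertion) and *13 (switch region 1400–1800, simulated
  as an in-place replacement that produces *no* junction signal — the
  case that must be recovered purely from the small-variant
  segmentation).
* **Cas9 excision** (`simulate_fragments()`): pool A cuts flank the
  locus (full-length fragments); pool B adds a cut between the genes.
  Each cut site carries its reference 21-mer as an implicit recognition
  sequence and *every* occurrence of that sequence on the haplotype is
  cut — a duplication that copies a recognition site therefore
  destroys full-length fragments, reproducing the artifact seen when
  hybrids re-introduce a gRNA site.
* **Errors** (`error_model()`): 3% mismatch, 2% insertion, 3% deletion
  per base, indel rates multiplied by 4 inside homopolymer runs ≥ 4,
  phred qualities around 12 — an R9.4-era stress level. Inserted bases
  duplicate their neighbour, the dominant ONT artifact. Reads are
  truncated with probability 0.1 (pore dropout), with the retained
  side biased 0.8 toward the 3′ adapter end because Cas9 stays bound
  on the 5′ side of the cut.
* **Background heterozygosity** (`add_background_het()`): 20
  heterozygous intergenic SNVs per diploid, the ~1 variant/kb density
  of real human genomes. These are what anchors read-backed phasing in
  genotypes where one allele is hemizygous over the defining variants
  (a deletion allele carries no het site inside the deletion — without
  background polymorphism no phasing tool has signal there).
* **Background reads** (`simulate_background()`): random-sequence reads
  emulating the adapter-ligation background of Cas9 enrichment; they
  must not survive the on-target filter.

What the generator does **not** emulate: signal-level (squiggle)
behaviour, basecaller-specific error correlations beyond homopolymers,
chimeric reads, and coverage waves from fragment-length biology.
Passing tests therefore demonstrate algorithmic correctness under a
realistic but idealized error process, not end-to-end performance on a
particular flow cell.

## Numerical and design choices

* **Coordinates** are 1-based closed internally (the IRanges/Biostrings
  convention of this language's ecosystem); BED output converts through
  `rtracklayer`, VCF is written 1-based via `vcfR`. This keeps interop
  bit-exact at the format boundary without fighting the container
  libraries.
* **Alignment** is delegated to minimap2, the field-standard long-read
  mapper, pinned to one thread for determinism; everything the package
  contributes (junction reduction, clustering, consensus, segmentation,
  star lookup) is its own code.
* **Probability example**: a 12A/8G column emits A with probability
  13/22 ≈ 0.59 — the Laplace-smoothed fraction, chosen so depth-0 and
  depth-1 columns cannot claim certainty.
* **Diplotype ordering**: within an allele, copies print in locus
  order joined by `+`; the two alleles print ordered by ascending copy
  count, then star number. This matches how reference laboratories
  print such genotypes (`*5/*4+*68`: the deletion allele first,
  `*1/*2+*13`: the single-copy allele first).
* **Tie-breaks**: a copy with no diagnostic signal is assigned to the
  gene whose annotated slot it occupies (via lift-over of the copy
  midpoint), falling back to gene 1. Zero-margin reads in phasing and
  re-assignment are left out rather than placed randomly.
* **Conflicting SVs on one allele**: the highest-support cluster wins;
  overlapping lower-support events are retained as secondary calls.
* **Inversions** are out of scope: inverted clip remappings are
  dropped, and only forward junctions are classified.
* **Phasing uses het SNVs only**; indel het sites are excluded from the
  read-allele matrix (indel observations on single reads are too
  error-prone at ONT indel rates) but remain genotyped and are phased
  implicitly through the allele consensus comparison.

## Problem sizes used in the test-suite

Unit tests run on a 6 kb miniature locus (two 800 bp genes, 94%
identity) where an operation is local, and on the full 28.2 kb locus
where the geometry matters (worked breakpoint examples, end-to-end
recovery). The end-to-end property re-simulates both reference
genotype classes (`*5/*4+*68`, `*1/*2+*13`) at 25X mean depth across
ten seeds each, which keeps the full suite within a desktop budget
while still exercising every stage on every run.

## Known limitations

* Exactly two source genes; more complex tandem arrangements (three or
  more copies, nested events) are out of scope.
* At most diploid phasing; no joint multi-sample calling.
* The hybrid star assignment keys on the detected switch region, not
  on exon-level annotation; definitions whose switch regions overlap
  would need finer evidence than this model provides.
* Star-allele similarity is plain Jaccard over variant keys. How extra
  (undefined) variants *should* influence ranking is genuinely open in
  the nomenclature; the metric and its tie cascade are surfaced as
  configuration rather than hidden.
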