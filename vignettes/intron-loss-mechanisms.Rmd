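---
title: "Measuring the mechanisms of intron loss and gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the mechanisms of intron loss and gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronevo)
```

## The inference problem

Given genome sequences and annotations for a five-taxon clade — two
closely related focal species and three successively deeper outgroups —
the package asks, for every intron position projected across orthologs:
was this intron inherited and then lost in one focal lineage, or gained
there? And for each inferred loss, does its signature (precision,
position, adjacency, boundary repeats, flanking GC) fit loss by reverse
transcription, by genomic deletion, or by non-homologous end joining?

The inference is deliberately parsimony-based, not probabilistic: with one
pair of focal species and three outgroups there is too little signal for
rate models, and Dollo parsimony (each intron arises once, can be lost any
number of times) is the standard instrument at this scale.

## Coordinates and intron identity

All internal coordinates are 0-based half-open; GFF3 I/O converts from and
to 1-based inclusive. An intron is identified by its host gene and its
**CDS offset** — the number of spliced-CDS nucleotides upstream — with
phase = offset mod 3. Two orthologous introns are *the same site* iff they
project to the same aligned-CDS column **and** have the same phase; a
one-nucleotide shift changes the phase and deliberately yields two
discordant sites rather than one conserved one. UTRs are ignored
throughout: "position in the mRNA" always means position in the spliced
CDS. This is an interpretive choice (annotation-independent and available
for every gene), and relative positions computed this way are slightly
right-shifted compared with a UTR-inclusive definition.

Gene models failing validation — CDS length not a multiple of three,
internal stop codons, ambiguous translation, out-of-bounds or overlapping
segments — are excluded up front and reported with reason codes, since
mis-annotated boundaries are the main source of spurious "losses" and
"gains". When a gene has several transcripts the longest spliced CDS is
kept: the one-to-one ortholog design assumes a single isoform per gene.

## Alignment and filtering

Orthologs are detected as reciprocal best BLAST hits (defaults E ≤ 1e-10,
identity ≥ 25%; ties on bitscore are broken by E-value, identity, then
lexicographic subject id, with a logged ambiguity flag). Proteins are
aligned globally under BLOSUM62 with affine gaps (open 10, extend 0.5) and
the alignment is codon-expanded, so intron positions are compared at
codon + phase resolution. Aligning in protein space and expanding to
codons is the robust reading when intron positions must be compared at
codon resolution; gaps are always whole codons, which keeps the
column-implies-phase relation intact. An externally computed protein
alignment can be supplied instead of the built-in aligner; with only one
aligner available the run proceeds in single-aligner mode (the
two-aligner consensus idea reduces to agreement between the built-in and
the supplied alignment when both are present).

Two filters precede any event call:

* **Flank similarity.** For each site, similarity over the 45 aligned-CDS
  columns on each side (gap columns count as mismatches; windows truncated
  by the alignment end use the available column count as denominator). A
  site with either side below 0.5 is discarded. The 0.5 default matches
  the first quartile of whole-alignment similarities in the data this
  procedure was designed around; `filter_sites()` reports the first
  quartile (type-7 linear interpolation) of the supplied similarities so
  the threshold can be re-derived per dataset. The 45-unit window is
  interpreted as aligned-CDS columns, not genomic bp — the natural unit
  once sites live in alignment coordinates; on gap-free flanks the two
  coincide.
* **Junction evidence.** Where splice-junction data (BED) are available,
  an extant intron at a discordant site must be confirmed by a junction
  matching both splice sites exactly with at least `min_reads` = 1
  supporting read (no read-count threshold is imposed beyond existence,
  as junction sets are usually pre-filtered). Missing junction data leave
  sites untouched: absence of evidence is not evidence against, and the
  condition is logged.

## Event calls

Dollo reconstruction places the single origin at the most recent common
ancestor of the tips carrying the intron and cuts the minimal set of
edges below it that explains the absences. `unknown` states (no ortholog,
or unalignable flanks in an outgroup) are uninformative: they neither
force nor block a loss. Gains are asymmetric by design: a putative gain
requires presence in exactly one species and **confirmed** absence in all
four others, so an `unknown` blocks a gain call but not a loss call. The
asymmetry mirrors the field's experience that recurrent losses masquerade
as gains when outgroup information is thin; it is a policy choice, not a
theorem. A terminal-branch "loss" at a single-presence site is the flip
side of a putative gain in the other focal species, and the pipeline
assigns each site to exactly one category.

Per-loss features are computed where they are defined:

* *Precision*: no gap column within 15 aligned-CDS columns on either side
  of the site. The window is not dictated by the biology — published
  analyses report indels "in the flanking exonic sequences" without a
  width — so 15 columns (five codons) is the package default and is
  configurable; gap columns are summed into `flank_indel_bp` otherwise.
* *Ordinal, relative position, intron length, boundary repeats* come from
  the intron-bearing ortholog — the lost intron no longer exists in the
  species that lost it.
* *Flanking GC* is measured in the species that lost the intron (that is
  where gene conversion would have acted), over up to 100 bp of spliced
  exonic sequence per side (50/200 variants available), pooled across the
  two sides; N bases leave the denominator. Windows never cross into
  neighbouring introns because they are taken on the spliced CDS — the
  reading adopted here for "flanking exonic sequences" (a genomic window
  could silently include intron sequence). *Relative GC* divides by the
  median flank GC over the same gene's conserved introns, removing gene-
  and species-level composition differences. *4-fold GC* restricts to
  third positions of codons whose first two bases determine a 4-fold
  family, after trimming partial codons at window edges.

## The adjacency nulls

Whether adjacent introns are co-lost more often than chance is tested two
ways, deliberately kept as separate code paths:

1. **Resampling**: draw the lost set's size uniformly without replacement
   from the pool of lost ∪ extant introns, count consecutive-ordinal
   pairs (a run of three adjacent losses counts as two pairs), repeat
   R = 10,000 times; p = (replicates ≥ observed)/R. The plain tail
   estimator is primary — it is the convention under which a never-reached
   observation reports p = 0 — and the shrunk (x+1)/(R+1) estimate is
   reported alongside.
2. **Exact independence null**: per gene, the distribution of
   adjacent-pair counts when k of n ordinals are chosen uniformly at
   random, computed by dynamic programming over positions, then convolved
   across genes into the clade-wide distribution of the total; the tail at
   the observed total is the independence probability.

For loss records the pre-loss gene structure is reconstructed by merging
the focal species' extant introns with the lost sites (mapped into focal
coordinates through the alignment) and ranking by offset, so lost and
extant introns share one ordinal scale.

Chi-square contrasts of loss rates use Pearson's statistic without
continuity correction (the correction is available by flag); rank tests
are exact for small untied samples and normal-approximate with tie and
continuity corrections otherwise.

## What the simulator emulates

`simulate_clade()` builds ancestral multi-exon genes (1–12 introns,
uniform; exons 90–240 bp; log-normal intron lengths with median ≈ 100 bp;
exonic GC 0.35 ± 0.05 per gene, AT-rich introns) and applies events on the
focal terminal branches:

* **Reverse transcription**: the target transcript is drawn with
  probability proportional to its intron count; with probability
  `rt_3prime_bias` the cDNA is partial, its length exponential with mean
  500 bp from the 3′ end, and the loss hits introns inside the covered
  span (all of them with probability `rt_coloss_prob`, one otherwise).
  Losses are precise; `gc_elevation_at_loss` converts A/T bases to G/C in
  the ±100 bp exonic flanks of the joined site, emulating conversion-tract
  GC bias.
* **Genomic deletion**: the intron plus 3 or 6 bp of upstream exon are
  removed. Real deletions need not respect the reading frame; multiples of
  three are used so the gene stays a valid model and the event remains
  visible as an alignment gap rather than wrecking the whole downstream
  alignment.
* **NHEJ**: a 2–6 bp direct repeat is planted at the intron boundary *in
  the ancestor* (so the intron-bearing ortholog exhibits it) before the
  intron is removed precisely in the focal species.

Gains copy a recorded donor-intron segment, wrap it in GT..AG, and insert
it into an exon; the emitted hit tables contain both the true source hit
and the trivial self-hit. Substitutions are uniform (Jukes–Cantor-like),
applied per terminal branch with fixed outgroup multipliers (PPA ×2,
DFA ×3, EHI ×5); stop codons arising anywhere are repaired at the third
position, and no indels occur outside the planted ones — so alignment
ambiguity cannot confound the precision classifier in tests. Ortholog hit
tables are synthesized from the simulator's own gene correspondence with
controlled E-values and identities, which lets the reciprocal-best-hit and
source filters run deterministically without an aligner.

What the simulator does **not** emulate: the extreme AT richness of real
social-amoeba genomes (≈78% AT), indel mutation outside planted events,
alternative splicing, paralogy, and annotation error beyond what the
validators reject. Passing recovery tests therefore demonstrates that the
pipeline measures what the generator planted — not that real genomes are
free of the confounders listed.

## Numerical and design choices

* Ambiguity codes other than N are normalised to N with a warning; N
  counts as non-GC and as a mismatch.
* Median = middle element (odd) or mean of the two middle elements.
* Quartiles use type-7 linear interpolation.
* Deterministic alignment tie-breaking is delegated to the alignment
  engine; scores are verified against an independent dynamic-programming
  oracle in the tests.
* Every random procedure takes an explicit seed and records it in its
  output; a fixed seed makes simulation and resampling bit-reproducible.
* A zero-margin 2×2 table returns chi2 = 0, p = 1 with a warning rather
  than an error, so an event-free run still reports.

Problem sizes used by the shipped checks (chosen to exercise ≥ 100 planted
losses where the directional recovery properties call for it, and small
exhaustive spaces elsewhere): recovery runs use 150-gene clades with 110 +
40 planted losses; the precision-classification check uses 60 genes with
45 pure-deletion losses at zero substitution rate; the resampling
calibration uses 200 null datasets of 30 genes with 40 uniform losses
each; the adjacency DP is verified exhaustively for all gene sizes n ≤ 8.

## Known limitations

* Sites lost in *both* focal species are invisible to the pairwise
  projection (there is no intron on either side), so loss sensitivity
  against simulated truth plateaus slightly below 1 when both branches
  carry losses; such sites surface as one ancestral-branch loss only when
  an outgroup-bearing site exists.
* The exact independence null conditions on the observed per-gene loss
  counts; the resampling null redistributes losses over the whole pool.
  They answer slightly different questions and coincide only for
  single-gene pools.
* Gain-source coverage is query (intron) coverage; subject coverage is
  not computed from tabular hit data.
* The per-branch substitution multipliers are fixed; branch lengths are
  not estimated.
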