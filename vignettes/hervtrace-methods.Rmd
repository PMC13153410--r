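---
title: "Methods: peptide-to-HERV origin tracing in hervtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide-to-HERV origin tracing in hervtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The procedure

`hervtrace` traces short query peptides — typically MHC-presented peptides
from immunopeptidomics — to the human endogenous retrovirus (HERV) loci
that could encode them, and ranks those candidate loci by RNA-seq read
support. The pipeline has four stages.

**1. ORF database construction.** The input reference is a set of provirus
regions: DNA sequences (FASTA, in region orientation) with genomic
locations (BED). Each region is translated in all six reading frames
(three offsets of the sequence, three of its reverse complement) under the
standard genetic code. An ORF here is a *maximal stop-free stretch* of one
frame translation — no start-codon requirement, because an MHC peptide can
derive from any in-frame stretch of translated sequence, not only from
AUG-initiated products. Within one region, ORFs with identical protein
strings are collapsed and the union of their genomic placements kept
(exact-duplicate deduplication; see "Design choices"). Each ORF's genomic
placement is computed arithmetically from its frame and amino-acid offset,
then verified by a round-trip: extracting the placement's
coding-orientation genomic DNA and translating it must reproduce the
protein exactly. This verification runs on every database build.

**2. Peptide search and back-mapping.** The retained matches are exactly
those at 100% identity over the peptide's full length; that criterion is
the definition of an exact substring occurrence, so the canonical search
backend is exact substring matching (`Biostrings::vmatchPattern`) over all
ORF proteins, reference and personalized alike. A BLASTP backend with the
short-peptide parameter preset is available for compatibility; because
heuristic seeding can drop short exact matches, it is documented and
tested as a subset of the exact backend, never as the canonical path. Each
hit at amino-acid offset $k$ in an ORF placed at $[S, E]$ maps to the
fragment
$[S + 3k,\; S + 3k + 3L - 1]$ on a plus-strand placement and
$[E - 3(k + L) + 1,\; E - 3k]$ on a minus-strand placement, where $L$ is
peptide length — so every fragment satisfies the span law
$end - start + 1 = 3L$. Fragments identical in
(peptide, chrom, start, end, strand) merge with their sources
concatenated, and are emitted as a GTF whose attributes carry the peptide,
source region/ORF ids, the whole-ORF span, the hit span and provenance.

**3. Quantification.** Per-sample coordinate-sorted indexed BAMs are
counted over the fragments. An alignment is credited to *every* fragment
it overlaps by at least `min_overlap` (default 1) reference bases,
strand-agnostically. Candidate fragments routinely nest and overlap (the
same peptide found at two offsets, or a short peptide inside a longer
one), so the largest-overlap disambiguation some counters apply would
silently zero nested fragments; crediting all overlapped features is the
deliberate choice here. By default only uniquely mapped reads count
(primary alignments with `NH` absent or 1, weight 1). With multi-mapped
counting enabled, secondary alignments are included; in fractional mode
each alignment of a read reporting `NH = k` counts $1/k$, so a read
overlapping one fragment per alignment contributes exactly 1 in total.
Counting jobs run one-per-sample with a configurable worker count; the
merged matrix is invariant to worker count and submission order, and
partial runs can be merged later provided no sample id repeats.

**4. Reporting.** Tumor/normal group sums per fragment give cohort-level
counts; the fragment maximizing total reads per peptide (optionally tumor
reads) is the reported most-expressed origin, with ties broken by smallest
(chrom, start, end, strand) so output is deterministic. Per-sample argmax
uses the same tie rule and prints the literal string `"no read"` for
zero-count cells. Three tables are emitted (per-fragment × sample counts;
most-expressed per peptide at tissue level; most-expressed per peptide and
sample), plus three heatmap layouts with a monotone color scale and
optional removal of all-zero rows. For validation, each fragment gets its
genomic context (default 60 nt per side, clipped at contig bounds, never
padded) extracted and — for minus-strand fragments — reverse-complemented
in full, so the coding subsequence always reads in frame left-to-right;
it is emitted both as separate columns and as a single
`UP[CODING]DOWN` string. Every emitted coding subsequence is re-translated
and checked against its peptide at run time. The bundled case-study table
(`inst/extdata/case_study_fragments.tsv`) shows the target format: its
printed sequences each contain the in-frame coding window at ~60 nt from
the start, which fixed the default flank.

## SNV personalization

A per-sample VCF layers accumulated single-nucleotide variants onto the
database. Only biallelic-expanded SNVs are used; indels, MNVs and symbolic
alleles are skipped with a counted warning (longer variants would shift
coordinates and are out of scope). Records must have FILTER `PASS` or `.`
by default. Each kept SNV's REF allele is checked against the region's own
base at that position — a mismatch aborts, because it indicates a
region/assembly mix-up rather than a variant. All of a region's SNVs are
applied jointly to one variant haplotype (multi-allelic sites expand
combinatorially, one haplotype per alternate combination); a one-at-a-time
mode exists by flag. Genotype and phasing fields are ignored — the
personalization question is "could this sample's genome encode the
peptide", for which presence of the allele suffices. Personalization is
additive: reference ORFs are never removed, although a real SNV could also
destroy a reference match; modeling loss would require genotype semantics
(homo/heterozygosity, somatic fraction) that the input VCF is not required
to carry, so it is documented as a limitation instead. Variant ORFs whose
protein already exists among the region's reference ORFs are collapsed
onto the reference entry; the rest carry a provenance tag
`sample:chrom:pos:ref>alt[;...]`. Placement round-trip verification is
restricted to reference-provenance ORFs, since variant ORFs intentionally
encode alleles absent from the reference sequence.

## Liftover

Coordinates can be lifted between assemblies through UCSC chain files. An
interval lifts only when one chain block contains it entirely; it then
maps contiguously with its length preserved and its strand composed with
the chain orientation. Intervals straddling block boundaries are rejected
with reason `"split"`, intervals with no covering chain with
`"unmapped"`, and rejections are returned in a table rather than silently
dropped — a fragment whose coordinates cannot be lifted exactly should be
re-derived on the target assembly, not approximated. The chain parser is
package-local because this single-block containment semantics (and the
explicit rejection reasons) is not what generic liftover utilities expose;
the generic utility serves as the cross-check in the test suite.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_orf_len` | 1 | aa | keep every stop-free stretch; short ORFs are noise for search but harmless |
| strand-call identity | 0.90 | fraction | position-wise identity needed to orient a region against the genome; below it the region is excluded with a warning, never guessed |
| `min_overlap` | 1 | bp | featureCounts-equivalent overlap rule |
| `count_multimapped` | FALSE | — | unique reads only unless asked; fractional mode implies multi-map |
| `fractional` | FALSE | — | weight $1/NH$ per alignment |
| `mapq` | 0 | — | no MAPQ filtering by default |
| `flank` | 60 | nt/side | matches the context length of the published validation sequences |
| `rank_by` | total | — | cohort ranking by total reads; tumor-read ranking by flag |
| blastp preset | see `query_config()` | — | the published short-peptide parameter set, reproduced exactly |

## Numerical and degenerate-input choices

- Only `N` is accepted as a DNA ambiguity code; other IUPAC letters are
  rejected loudly. `N`-containing codons translate to `X` (even when the
  codon would be unambiguous), and `X` never matches a query residue.
- Peptides must be ≥ 3 residues over the 20 standard amino acids;
  isoleucine and leucine are *not* folded together despite their equal
  mass — sequences are treated literally.
- All counts are exact integers in unique mode (asserted); fractional
  counts are exact rationals of the form $m/NH$ and compared exactly in
  tests (no tolerance needed since $NH$ values are tiny).
- Empty inputs are legal where they are meaningful: an empty peptide hit
  set produces a valid empty GTF and headers-only tables with success
  status; an empty region set is an error.
- Database serialization carries a format-version header and refuses
  foreign files.

## The synthetic-data generator

`make_fixture_cohort()` is first-class, tested code, not a throwaway
fixture. It emulates, at toy scale, the structure of the real inputs: a
two-contig 20-kb genome; six provirus-like regions of 600 bp; planted
in-frame coding windows for the query peptides; per-sample tumor/normal
BAMs; and a single-sample VCF. It always includes the three failure modes
the method must survive: the same peptide planted on both genomic strands,
a nested fragment pair (a 15-mer and its internal 9-mer), and a duplicated
locus driving `NH = 2` multi-mapping — plus a near-miss decoy (one
mismatched residue) whose enabling SNV turns it into a true coding window
only in the personalized database, and one region annotated on the BED
minus strand to exercise region orientation.

Reads are placed deterministically (staggered positions inside each
fragment) rather than sampled, so count recovery is exact, not
statistical; the truth matrices are recomputed from the placed reads by
plain interval arithmetic, independently of the package's counting path.
All generators are pure functions of their seed (byte-identical reruns).

What the fixtures deliberately do *not* emulate — and hence what passing
tests do not demonstrate about real data: sequencing error and base
qualities, splice-aware alignments (all simulated CIGARs are simple
matches), realistic expression distributions, repeat-induced mapping
ambiguity beyond the planted duplication, and the scale of the real
3173-region reference. Problem sizes in the test suite and acceptance
script (tens of regions, hundreds of ORFs per random database, thousands
of oracle comparisons) were chosen as the smallest sizes at which every
code path — both strands, nesting, duplication, personalization,
multi-mapping — is exercised.

## Design choices where the design was open

- **Exact arithmetic instead of alignment for ORF localization.** Since
  the package generates the ORFs itself, their genomic coordinates are
  known exactly from frame and offset; re-deriving them with a
  translated-alignment tool would add version-dependent nondeterminism to
  a step whose answer is closed-form. The round-trip translation check
  replaces the alignment as verification.
- **Exact-duplicate ORF collapse.** Deduplication thresholds below 100%
  identity would delete searchable sequence content and break the
  100%-identity filter, so only identical proteins collapse, per region.
  Regions are deduplicated independently: the same protein in two regions
  is two entries, because the two loci are distinct origin hypotheses.
- **BED strand takes precedence** over genome-derived strand annotation
  when both exist; re-derivation (`annotate_strands()`) is applied only to
  regions lacking an annotation.
- **Cohort ranking by total reads**, with tumor-read ranking behind a
  flag: summing tumor and normal reads is the cohort criterion, and
  no tumor/normal ratio threshold is imposed — distinguishing
  tumor-specific from tumor-associated patterns is left to the reader of
  the tables, which show both group sums.
- **Paired-end handling**: each alignment record counts independently
  (single-end model). A template-level mode would halve counts for
  properly paired data but requires mate-resolution policy decisions that
  the fragment-level question does not need.
- **Threads default to a single worker**, not a fixed large count;
  `--workers` overrides. Results are worker-invariant by construction.

## Known limitations

- Insertions, deletions and structural variants are not personalized.
- No normalization (TPM/size factors) or differential-expression
  statistics: reported values are raw read counts, as the origin-ranking
  question only needs within-peptide comparisons on the same cohort.
- The BLASTP backend's pre-filter hit lists depend on the external BLAST
  version; only its post-filter subset relation to the exact backend is
  guaranteed.
- Liftover rejects (rather than splits) intervals crossing chain blocks;
  fragments in rearranged regions must be re-derived on the target
  assembly.
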