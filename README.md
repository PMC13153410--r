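# hervtrace

Tracing immunopeptidomic peptides to their endogenous-retrovirus genomic
origins, with RNA-seq expression support.

## The problem

Human endogenous retroviruses (HERVs) make up roughly 8% of the genome.
Normally silent, some proviral loci are transcribed in tumors and can yield
MHC-presented peptides (MPPs) — candidate tumor-specific or tumor-associated
antigens. Immunopeptidomics (LC-MS/MS) gives you the peptide sequence, but
not where in the genome it came from; a short 9-mer can be encoded by many
proviral loci, and choosing the wrong origin wastes downstream validation
effort. `hervtrace` answers two questions for each query peptide:

1. **Which genomic HERV fragments could encode this peptide?** Every
   provirus region is translated in all six reading frames; open reading
   frames (ORFs) are the maximal stop-free stretches between stop codons.
   A peptide of length `L` matches an ORF only at 100% identity over its
   full length — i.e. as an exact substring — and each match is mapped back
   to the exact genomic interval of `3L` nucleotides (the *HERV fragment*)
   that encodes it, with its coding strand.
2. **Which of those fragments is actually expressed?** Coordinate-sorted
   RNA-seq BAMs for tumor and normal samples are counted over the candidate
   fragments (featureCounts-style: an alignment is credited to every
   fragment it overlaps by at least 1 bp; multi-mapped reads can be counted
   fractionally at `1/NH`). The fragment with the highest total read count
   per peptide, at cohort and at individual-sample level, is reported as
   the most plausible origin, together with a validation-ready DNA sequence
   context for wet-lab follow-up.

Per-sample single-nucleotide variants (VCF) can be layered onto the ORF
database, so a peptide created by a somatic or germline SNV inside a HERV
region is still traceable in that sample.

The package is a library plus a thin command-line front-end
(`inst/scripts/hervtrace`) mirroring the three-step workflow:
`build-db` → `annotate` (GTF of candidate fragments) → `quantify`
(fragment × sample count matrix) → `report` (three summary tables and
three heatmap layouts). A deterministic synthetic-data generator
(`make_fixture_cohort()`) builds a toy genome with planted peptides, reads,
SNVs and a machine-readable truth set, so everything is testable offline.

## Core conventions

- Coordinates are 1-based inclusive on the reference plus strand
  everywhere a user sees them; strandedness is a flag, never a coordinate
  transformation. BED input is converted at the boundary.
- A fragment always satisfies the span law `end − start + 1 = 3L`.
- Every reported fragment and validation sequence is verified by
  translation round-trip: the coding-orientation DNA must translate back to
  the peptide exactly. Codons containing `N` translate to `X`, which
  matches no query residue.
- Exact substring search is the canonical peptide-matching backend (the
  100%-identity full-length filter *is* exact substring occurrence). A
  `blastp` backend with the short-peptide parameter preset
  (`-word_size 3 -gapopen 9 -gapextend 1 -matrix PAM30 -threshold 16
  -comp_based_stats 0 -window_size 15 -evalue 0.05`) is provided for
  compatibility and is always a subset of the exact backend.

## Worked example

Entirely self-contained (the fixture generator builds the genome, regions,
reads and truth set):

```r
library(hervtrace)

fx <- make_fixture_cohort(file.path(tempdir(), "demo"), seed = 1)
regions <- load_reference(fx$regions_fa, fx$regions_bed, assembly = "toy")
db <- build_database(regions)
db
#> ORF database (toy): 6 region(s), 325 ORF(s), 329 placement(s)

peptides <- read_peptides(fx$peptides_fa)
hits <- find_peptide_hits(peptides, db)
fragments <- merge_fragments(hit_to_fragment(hits, db))
fragments[, c("peptide_id", "peptide", "chrom", "start", "end", "strand")]
#>   peptide_id         peptide chrom start  end strand
#> 1        Q_A       AVLLPQPPK  ctg1  1285 1311      +
#> 2        Q_A       AVLLPQPPK  ctg1  4285 4311      +
#> 3        Q_A       AVLLPQPPK  ctg2  1285 1311      -
#> 4        Q_B NEAIEQVRAICLRAW  ctg1  2776 2820      +
#> 5    Q_Bnest       IEQVRAICL  ctg1  2785 2811      +
#> 6        Q_C       GILLPQPPK  ctg2  2785 2811      -

fc <- run_quantification_jobs(fx$manifest, fragments, counting_mode(),
                              workers = 2)
tables <- build_summary_tables(fc, genome = fx$genome,
                               out_dir = file.path(tempdir(), "report"))
tables$most_expressed_tissue[, c("peptide_id", "fragment_id", "tumor_reads",
                                 "normal_reads", "total_reads", "strand")]
#>   peptide_id       fragment_id tumor_reads normal_reads total_reads strand
#> 1        Q_A ctg1:1285-1311(+)          10            4          14      +
#> 2        Q_B ctg1:2776-2820(+)          12            6          18      +
#> 3    Q_Bnest ctg1:2785-2811(+)          12            6          18      +
#> 4        Q_C ctg2:2785-2811(-)           6            0           6      -
```

Reading the output: peptide `Q_A` is encodable at three loci (including a
minus-strand locus — note the 27-nt span on all of them, `3 × 9`); the
cohort-level most-expressed origin is `ctg1:1285-1311` with 10 tumor and 4
normal reads. A fragment expressed in tumor but not normal samples (like
`Q_C`'s) is the pattern one would pursue as a candidate tumor-specific
antigen. `tables$most_expressed_per_sample` gives the same call per
individual sample, printing the literal `"no read"` where a peptide has
zero counts in a sample, and `render_heatmap()` draws the three heatmap
layouts (peptides × groups, fragments × groups, fragments × samples).

The same pipeline from a shell:

```sh
hervtrace build-db  --regions-fa ref/regions.fa --regions-bed ref/regions.bed \
                    --assembly toy --db ref.db
hervtrace annotate  --db ref.db --peptides peptides.fa --gtf frags.gtf
hervtrace quantify  --manifest bams/manifest.tsv --gtf frags.gtf \
                    --out counts.rds --workers 4
hervtrace report    --counts counts.rds --out-dir report --genome genome.fa
```

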