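---
title: "Comparative screens and bulk curation of gene annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative screens and bulk curation of gene annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annocure)
library(dplyr)
```

## The problem

Draft gene annotations of non-classical model organisms -- nematodes such as
*Pristionchus pacificus* are the motivating case -- are built by automated
pipelines that mix ab-initio gene prediction with transcript and homology
evidence. Such annotations carry recurring, systematic error classes:

* **artificial gene fusions**, where one predicted model erroneously spans
  two real genes (often via overlapping UTRs in gene-dense regions), so the
  predicted protein is roughly the concatenation of two real proteins;
* **spurious antisense models**, single-exon predictions lying on the strand
  opposite a well-supported gene, with no homology and no strand-specific
  expression of their own -- these inflate the species-specific orphan gene
  (SSOG) count and contaminate studies of novel gene origin;
* **mis-sized members of large gene families** (collagens, C-type lectins,
  ...), where a truncated or fused model is betrayed by its length relative
  to its family.

annocure implements the comparative-genomic screens that enrich for each of
these error classes, a curation engine that applies the resulting
keep/remove/replace decisions in bulk, and a synthetic-fixture generator
that plants each defect class with a known truth table so the whole
pipeline is testable without any external data.

## The screens

### Ortholog protein-length ratios

For one-to-one orthologs between the focal species and a well-curated
reference, protein lengths are strongly correlated, so a large length ratio
is a cheap, powerful anomaly signal. For each ortholog pair the screen takes
the *longest isoform* on both sides (ties broken by lexicographically
smallest protein id, for determinism) and computes

$$r = L_\mathrm{focal} / L_\mathrm{reference}$$

on integer amino-acid lengths, with no pseudo-counts. A pair is a candidate
when $r \ge c$ (too-long) or $r \le 1/c$ (too-short), with $c = 2$ by
default. The boundary is *inclusive*: the sources describing this kind of
screen use "two-fold difference" and "more than two-fold" interchangeably,
so we flag $r = 2$ exactly and expose `strict = TRUE` for the open-boundary
variant. Both directions are screened and the direction is recorded, since
too-short candidates (truncations, split genes) are as informative as
too-long ones (fusions).

```{r lev8}
pairs <- build_ortholog_pairs(
  tibble(focal_gene = "PPA00494", reference_gene = "lev-8"),
  tibble(protein_id = "PPA00494.p", gene_id = "PPA00494", length = 1094L),
  tibble(protein_id = "LEV-8.p", gene_id = "lev-8", length = 531L))
tidy(screen_length_outliers(pairs, compute_correlation = FALSE))
```

A 1094-aa focal protein against a 531-aa reference ortholog has ratio 2.06
and is flagged too-long -- the classic signature of a gene fused with its
neighbour.

### Atypical domain combinations

A fusion of two single-domain genes creates a protein whose *pair* of
domain families may never co-occur in related species. The screen counts,
per species, how many proteins contain each unordered pair of distinct
Pfam families (`"pairs"` mode, the default). A focal protein is a candidate
when it carries at least one pair that is (i) absent from every reference
species and (ii) rare in the focal species itself (fewer than 10 focal
proteins by default). Two deliberate choices:

* the census counts **proteins, not domain instances** -- a collagen with
  thirty collagen domains contributes once;
* granularity is ambiguous in principle ("domain combination" could mean
  the whole architecture), so a `"full-set"` mode is provided; censuses
  carry their mode and cannot be mixed.

Genuine lineage-specific domain shuffling also lands in this screen, which
is why its hits are curation *candidates*, not verdicts.

### Gene-family length deciles

Within each screened Pfam-defined family, per-family length thresholds are
computed by the nearest-rank rule: the first decile is the value at rank
$\lceil 0.1\,n \rceil$ and the eighth decile the value at rank
$\lceil 0.8\,n \rceil$ of the sorted lengths. Members strictly below the
first or strictly above the eighth decile are flagged, so roughly the
bottom 10% and top 20% of every family are selected while boundary members
are kept. Families under 10 members are skipped with a message -- deciles
are meaningless there, and the screen is intended for highly abundant
families. A protein in several screened families is flagged if it is an
outlier in *any* of them, with each triggering family reported.

Note the screen is relative by construction: it always selects about 30%
of every screened family, so (unlike the other screens) a planted-defect
truth table can only be evaluated for recall, not precision.

### Orphan genes and strand-aware classification

A focal gene is called an SSOG when no isoform has a BLASTP hit with
e-value below 0.001 in any reference set designated as homology evidence
("no hit" is read as "no hit below the cutoff"; the alternative reading --
no hit at all -- would make the call depend on BLAST's reporting
threshold). Hits in a focal-transcriptome ORF set do not count against
orphan status but mark transcriptomic support.

Unsupported SSOGs are then classified by a priority rule, using >= 1 bp of
strand-aware exon overlap (no threshold is stated for this anywhere, and
1 bp is the least arbitrary choice):

1. `antisense_cds` -- an SSOG exon overlaps another gene's CDS on the
   opposite strand; CDS outranks UTR because the two classes are reported
   disjointly and a rank is required;
2. `antisense_utr` -- opposite-strand overlap with UTR only;
3. `other` -- same-strand overlap with another model; such entangled loci
   need locus-level judgement, not a rule. Antisense checks run first: an
   exon that is antisense to a CDS is the stronger, more specific artifact
   signal even if the model also touches a same-strand neighbour;
4. `some_expression` -- same-strand coverage (depth > 0) over at least 50%
   of the SSOG's exonic bases. The 50% default stands in for what is, in
   practice, a visual judgement; it is configurable;
5. `no_support` -- otherwise.

The default removal policy removes `no_support`, `antisense_cds` and
`antisense_utr` and keeps the rest; it is a configurable lookup table, not
hard-wired.

```{r classify}
host <- tibble(
  seqid = "chrI",
  start = c(1001L, 2001L, 1051L, 2001L, 1001L, 2201L),
  end   = c(1500L, 2300L, 1500L, 2200L, 1050L, 2300L),
  strand = "+", type = c("exon", "exon", "cds", "cds", "utr5", "utr3"),
  transcript_id = "host.t1", gene_id = "host")
orphan <- tibble(seqid = "chrI", start = 1101L, end = 1160L, strand = "-",
                 type = c("exon", "cds"), transcript_id = "anti.t1",
                 gene_id = "anti")
ann <- annotation_set(bind_rows(host, orphan))
classify_ssogs(
  tibble(gene_id = "anti", is_ssog = TRUE, has_orf_support = FALSE), ann) |>
  select(gene_id, category, triggering_gene)
```

Percentages in all category summaries are rounded half away from zero to
integers, matching how such tables are conventionally printed.

## The curation engine

Curation decisions are rows of a table: `keep`, `remove`, or `replace` with
one or more transcripts from an evidence annotation (typically assembled
RNA-seq transcripts). Replacement promotes each transcript to a new
single-transcript gene named `<old_gene_id>.split<N>` -- a deterministic,
provenance-preserving scheme, so a fused model replaced by its two
underlying transcripts yields `X.split1` and `X.split2` and the gene count
obeys

$$n_\mathrm{after} = n_\mathrm{before} - n_\mathrm{removed}
  - n_\mathrm{replaced} + \sum_i s_i$$

exactly, where $s_i$ are replacement sizes. Neighbourhood edits are never
inferred: if correcting one gene implies touching its neighbour, that is a
second explicit action. Promoted genes may overlap retained neighbours;
since the merge semantics of such overlaps are genuinely unspecified, the
engine permits them and warns on same-strand span overlap.

Two statistics summarise an annotation: the gene count, and coding
megabases measured as the *genomic union* of CDS bases (isoforms never
double-counted; near-constancy of this measure across annotation versions
is the expected behaviour of a genome-level union, which is why union was
chosen over a per-isoform sum). The read-assignability metric counts a
whole alignment as assigned when it overlaps >= 1 bp of exon of exactly
one gene, unstranded; overlap with two or more genes is ambiguous and
unassigned. This is a deliberate simplification of feature-counting tools:
whole alignments, no fractional assignment, no strand handling.

## The synthetic fixture generator

`simulate_annotation()` builds the study conditions every test runs under:
non-overlapping genes laid along genome-less sequences with uniform exon
counts 1--5, exons 100--600 bp, introns 50--200 bp, UTRs 30--90 bp and
intergenic gaps 200--1000 bp -- arbitrary but fixed defaults, all
overridable; about 20% of multi-exon genes get a second, 3'-truncated
isoform so longest-isoform selection is exercised. Every gene has a
reference ortholog of identical length, homology hits in every reference
BLAST set, ORF-support hits, strand-specific coverage over its exons, and
one or two domain families from a small vocabulary whose every pairwise
combination exists in all reference species. Consequently a defect-free
bundle produces zero candidates in every screen, and each planted defect
is the *only* signal its screen can find:

* **fusions** merge two adjacent same-strand genes (the upstream part never
  longer than the downstream part, and the ortholog table keeping the
  upstream part's reference, so the fused ratio is provably >= 2); the two
  original transcripts move to the evidence set and a replace action is
  suggested;
* **antisense orphans** are single-exon, fully coding genes planted
  opposite a host CDS or inside a host UTR, with no BLAST hits and no
  coverage on their own strand;
* **atypical combinations** add two novel domain families to one clean
  protein;
* **family outliers** are single-exon family members whose protein length
  (40--60 aa or 1200--1500 aa) lies far outside the clean members' 250--350
  aa band.

Protein sequences are random amino-acid strings of the required lengths:
homology is asserted through the BLAST fixture, not through alignable
sequence. That is the main sense in which these fixtures are easier than
real data -- real screens face borderline e-values, fragmented assemblies,
overlapping real genes and isoform ambiguity that the generator does not
model. Passing the recovery tests therefore demonstrates that the screen
logic is correct, not that real-data candidate lists will be clean.

All randomness flows from one mandatory seed; the same config yields
byte-identical output files (written GFF3 carries no timestamp comments).

## Numerical and interface choices

* Coordinates are GFF3-convention 1-based inclusive everywhere in memory;
  half-open conversion happens only inside interval computations (IRanges)
  and on BED read/write.
* Domain hits are filtered at read time on the per-domain *independent*
  e-value (the per-domain quantity in a HMMER domain table), cutoff 0.001.
* Protein lengths exclude a trailing `*` stop symbol if the FASTA carries
  one.
* Isoform-to-gene mapping in FASTA headers follows the fixture convention
  `>protein_id gene=<gene_id>`, falling back to the protein id; adapters
  for other header dialects are the caller's responsibility.
* All report percentages are integer, rounded half away from zero; all
  output tables are sorted so repeated runs are byte-identical.

## Problem sizes used in the test-suite

The standard study bundle used by the recovery tests has 200 genes with 5
planted fusions, 5 antisense-CDS orphans, 3 antisense-UTR orphans, 4
atypical combinations and 4 family outliers among 40 members of one
screened family; decile calibration uses one simulated family of 10,000
i.i.d. continuous lengths, on which the nearest-rank rule flags 9.99%
short and 20.0% long. These sizes were chosen so the whole suite exercises
every code path at desk scale.

## Limitations

* Orthology inference, BLAST, HMMER, read alignment and BUSCO scoring are
  consumed as tabular inputs, never invoked.
* The curation engine executes decisions; it does not make them. The human
  judgement step between candidate lists and action tables is out of
  scope.
* The assignability metric is not a drop-in replacement for
  fragment-counting tools; it is a comparable, simpler statistic for
  before/after comparisons of the same data.
* GTF and GenBank dialects are not parsed; input is GFF3.
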