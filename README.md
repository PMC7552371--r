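# annocure

Comparative-genomic screens and bulk curation for draft gene annotations.

Automated gene annotation pipelines leave systematic errors behind:
**artificial gene fusions** (one predicted model spanning two real genes,
its protein roughly the concatenation of both), **spurious antisense
models** that masquerade as species-specific orphan genes (SSOGs), and
**mis-sized members of large gene families**. annocure is for genome
projects -- the motivating case is nematode genomics, where a draft
annotation is compared against a highly curated relative -- that want to
find these suspicious gene models systematically, hand them to curators,
and then apply the resulting decisions in bulk.

## What it computes

* **Ortholog length screen** — for one-to-one orthologs, the ratio
  *r* = *L*<sub>focal</sub>/*L*<sub>reference</sub> of longest-isoform
  protein lengths; candidates are pairs with *r* ≥ *c* or *r* ≤ 1/*c*
  (default *c* = 2, boundary inclusive), plus Pearson's correlation of the
  two length sets.
* **Atypical domain combinations** — a census of unordered Pfam-family
  pairs per proteome; focal proteins carrying a pair absent from every
  reference species and present in < 10 focal proteins are candidates.
* **Family length deciles** — within each Pfam-defined family (≥ 10
  members), members below the 1st or above the 8th nearest-rank decile of
  the length distribution (≈ the bottom 10% and top 20%).
* **SSOG calling and classification** — genes with no BLASTP hit
  (e < 0.001) in any homology reference set; unsupported SSOGs are
  classified by strand-aware overlap (`antisense_cds` > `antisense_utr` >
  `other` > `some_expression` > `no_support`) and a configurable removal
  policy proposes curation actions.
* **Curation engine** — applies keep/remove/replace-with-transcripts
  actions (replacements promoted to genes named `<old>.split<N>`), writes
  GFF3, and recomputes statistics: gene counts, coding megabases as the
  genomic union of CDS bases, screen-count deltas, and a read-assignability
  percentage (an alignment is assigned iff it overlaps exons of exactly one
  gene).
* **Synthetic fixtures** — a seeded generator that builds an annotation,
  proteome, ortholog table, per-species domain tables, BLAST hits and
  strand-specific coverage with each defect class planted and recorded in a
  truth table.

Everything is tibble-in/tibble-out and pipe-friendly; screen objects have
`tidy()`, `glance()` and `autoplot()` methods. Formats handled: GFF3,
protein FASTA, BLAST outfmt-6, HMMER domtblout, BED coverage, TSV/YAML.

## Worked example

Simulate a 60-gene annotation with two planted fusions and one antisense
orphan, then run the length screen, classify orphans, and apply the
suggested corrections:

```r
library(annocure)
library(dplyr)

cfg <- fixture_config(n_genes = 60, n_family_members = 20, n_fusions = 2,
                      n_antisense_cds_ssogs = 1, seed = 42)
b <- simulate_annotation(cfg)

pairs <- build_ortholog_pairs(b$ortholog_table, b$proteins,
                              b$reference_proteins)
screen <- screen_length_outliers(pairs)
glance(screen)
#> # A tibble: 1 × 5
#>   n_pairs pearson_r cutoff strict n_candidates
#>     <int>     <dbl>  <dbl> <lgl>         <int>
#> 1      58     0.770      2 FALSE             2
tidy(screen)
#> # A tibble: 2 × 6
#>   focal_gene reference_gene direction focal_length reference_length ratio
#>   <chr>      <chr>          <chr>            <int>            <int> <dbl>
#> 1 PPA00022   CEL_PPA00022   too-long           313               58  5.40
#> 2 PPA00034   CEL_PPA00034   too-long           953              219  4.35
```

The two flagged genes are exactly the planted fusions: their proteins are
the concatenation of two real genes, so they are > 2-fold longer than their
reference orthologs. The orphan screen recovers the planted antisense
model and names the sense gene it shadows:

```r
roles <- setNames(c(rep("homology", 4), "orf_support"),
                  c(cfg$homology_sets, cfg$orf_set))
ssogs <- call_ssogs(b$proteins, b$blast_hits, roles)
cl <- classify_ssogs(filter(ssogs, is_ssog), b$annotation, b$coverage)
ssog_category_summary(cl)
#> # A tibble: 1 × 3
#>   category          n percent
#>   <chr>         <int>   <dbl>
#> 1 antisense_cds     1     100
```

Applying the suggested replace actions splits each fused model into its two
underlying transcripts (59 − 2 + 4 = 61 genes) while the coding-base union
is unchanged:

```r
curated <- apply_curation_actions(b$annotation, b$suggested_actions,
                                  b$evidence)
rbind(annotation_stats(b$annotation), annotation_stats(curated))
#> # A tibble: 2 × 4
#>   version_label        n_genes n_transcripts coding_mb
#>   <chr>                  <int>         <int>     <dbl>
#> 1 synthetic-v1              59            71    0.0508
#> 2 synthetic-v1-curated      61            73    0.0508
```

A YAML-driven workflow (`screen_all()`, `run_curation()`) and a
command-line wrapper (`inst/scripts/annocure` with `simulate`, `screen`,
`curate`, `stats` subcommands) tie the screens together and write sorted,
reproducible TSV/JSON reports. See the vignette
(`vignettes/annotation-screens.Rmd`) for the models, parameter choices and
limitations.

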