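# Writers that serialise a fixture bundle into the external formats the
# toolkit consumes, so the full read-path is exercised end to end.

#' Write a protein table as FASTA
#'
#' Headers follow the `<protein_id> gene=<gene_id>` convention that
#' [read_protein_fasta()] parses.
#'
#' @param proteins protein table with sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  assert_cols(proteins, c("protein_id", "gene_id", "sequence"),
              "protein table")
  if (anyNA(proteins$sequence)) abort("protein table has missing sequences")
  aa <- Biostrings::AAStringSet(setNames(
    proteins$sequence,
    paste0(proteins$protein_id, " gene=", proteins$gene_id)))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Write BLAST hits as 12-column tabular (outfmt 6)
#'
#' @param hits hit tibble (as produced by [read_blast_tab()] or the fixture
#'   generator); the `subject_set` column is dropped, one file per set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  hits |>
    select("query_id", "subject_id", "pident", "align_length", "mismatches",
           "gap_opens", "query_start", "query_end", "subject_start",
           "subject_end", "evalue", "bitscore") |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write domain hits in the HMMER3 domtblout dialect
#'
#' Emits the whitespace-delimited 23-column per-domain table that
#' [read_domtbl()] parses (profile searched against proteins; the
#' independent e-value column carries the hit's e-value).
#'
#' @param hits tibble with `protein_id`, `domain_family`, `evalue`,
#'   `env_start`, `env_end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_domtbl <- function(hits, path) {
  assert_cols(hits, c("protein_id", "domain_family", "evalue", "env_start",
                      "env_end"), "domain hits")
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  rows <- sprintf(
    "%s - %d %s %s %d %.2g %.1f %.1f %d %d %.2g %.2g %.1f %.1f %d %d %d %d %d %d %.2f -",
    hits$protein_id, hits$env_end + 10L, hits$domain_family,
    hits$domain_family, hits$env_end - hits$env_start + 1L,
    hits$evalue, 100.0, 0.1, 1L, 1L, hits$evalue, hits$evalue, 95.0, 0.1,
    1L, hits$env_end - hits$env_start + 1L,
    hits$env_start, hits$env_end, hits$env_start, hits$env_end, 0.95)
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

#' Write strand-tagged coverage as BED6
#'
#' @param coverage tibble (`seqid`, `start`, `end`, `strand`, `depth`;
#'   1-based inclusive, converted to BED's 0-based half-open on write).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(coverage, path) {
  assert_cols(coverage, c("seqid", "start", "end", "strand", "depth"),
              "coverage table")
  coverage |>
    mutate(bed_start = .data$start - 1L, name = ".") |>
    select("seqid", "bed_start", "end", "name", "depth", "strand") |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Serialise a fixture bundle to disk
#'
#' Writes every external file the screens and the curation engine read:
#' annotation and evidence GFF3, focal and reference protein FASTA, ortholog
#' TSV, one domtblout per species, one BLAST table per subject set, coverage
#' BED, the truth table, suggested curation actions and the generator config
#' as YAML.
#'
#' @param bundle a `fixture_bundle` from [simulate_annotation()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c(annotation = p("annotation.gff3"), evidence = p("evidence.gff3"),
             proteins = p("proteins.fasta"),
             reference_proteins = p("reference_proteins.fasta"),
             orthologs = p("orthologs.tsv"), coverage = p("coverage.bed"),
             truth = p("truth.tsv"), actions = p("suggested_actions.tsv"),
             config = p("config.yaml"))
  write_gff3(bundle$annotation, paths["annotation"])
  write_gff3(bundle$evidence, paths["evidence"])
  write_protein_fasta(bundle$proteins, paths["proteins"])
  ref <- bundle$reference_proteins |>
    mutate(sequence = purrr::map_chr(.data$length, function(n) {
      paste(rep("A", n), collapse = "")  # placeholder residues; only lengths matter
    }))
  write_protein_fasta(ref, paths["reference_proteins"])
  readr::write_tsv(bundle$ortholog_table, paths["orthologs"],
                   progress = FALSE)
  for (sp in names(bundle$domain_hits)) {
    f <- p("domains_", sp, ".domtbl")
    write_domtbl(bundle$domain_hits[[sp]], f)
    paths[paste0("domains_", sp)] <- f
  }
  for (set in unique(bundle$blast_hits$subject_set)) {
    f <- p("blast_", set, ".tsv")
    write_blast_tab(bundle$blast_hits |> filter(.data$subject_set == set), f)
    paths[paste0("blast_", set)] <- f
  }
  write_coverage_bed(bundle$coverage, paths["coverage"])
  readr::write_tsv(bundle$truth, paths["truth"], progress = FALSE)
  readr::write_tsv(bundle$suggested_actions, paths["actions"],
                   progress = FALSE)
  yaml::write_yaml(unclass(bundle$config), paths["config"])
  invisible(paths)
}
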