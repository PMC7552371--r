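#' Read BLASTP tabular hits (outfmt 6)
#'
#' Reads the 12-column tab-separated BLAST format (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) and tags
#' every hit with the reference set it was searched against, so homology
#' evidence and focal-transcriptome ORF support can be told apart downstream.
#'
#' @param path path to a tabular BLAST file.
#' @param subject_set label of the reference proteome/ORF set searched.
#' @return a tibble of hits, one per row, in file order; empty files give an
#'   empty tibble with the full column set.
#' @export
read_blast_tab <- function(path, subject_set) {
  stopifnot(is.character(subject_set), length(subject_set) == 1)
  cols <- c("query_id", "subject_id", "pident", "align_length", "mismatches",
            "gap_opens", "query_start", "query_end", "subject_start",
            "subject_end", "evalue", "bitscore")
  # readr's parse warning is superseded by the explicit problems() check
  hits <- suppressWarnings(
    readr::read_tsv(path, col_names = cols,
                    col_types = "ccdiiiiiiidd", progress = FALSE))
  pb <- readr::problems(hits)
  if (nrow(pb) > 0) {
    abort(sprintf("malformed BLAST tabular row at line %d (column %d): %s",
                  pb$row[1], pb$col[1], pb$actual[1]))
  }
  if (any(hits$evalue < 0)) abort("negative e-value in BLAST table")
  hits |>
    mutate(subject_set = subject_set, .after = "subject_id")
}

#' Read a HMMER3 per-domain hit table (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by `hmmsearch
#' --domtblout` (profiles searched against proteins: the target is the
#' protein, the query the domain profile). Hits are filtered at read time on
#' the per-domain independent e-value; rows at or above the cutoff are
#' dropped and their count reported via a message.
#'
#' @param path path to a domtblout file.
#' @param evalue_cutoff significance cutoff; hits with independent e-value
#'   `>= evalue_cutoff` are dropped. Default 0.001.
#' @return a tibble with `protein_id`, `domain_family` (profile accession,
#'   falling back to the profile name when no accession is recorded),
#'   `evalue`, `env_start`, `env_end`.
#' @export
read_domtbl <- function(path, evalue_cutoff = 0.001) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(tibble(protein_id = character(), domain_family = character(),
                  evalue = double(), env_start = integer(),
                  env_end = integer()))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(toks) < 22
  if (any(short)) {
    abort(sprintf("truncated domtblout row at line %d", line_no[short][1]))
  }
  fld <- function(i) vapply(toks, `[[`, "", i)
  acc <- fld(5)
  hits <- tibble(
    protein_id = fld(1),
    domain_family = ifelse(acc == "-", fld(4), acc),
    evalue = as.numeric(fld(13)),
    env_start = as.integer(fld(20)),
    env_end = as.integer(fld(21))
  )
  if (anyNA(hits$evalue)) {
    abort(sprintf("non-numeric i-Evalue at line %d",
                  line_no[which(is.na(hits$evalue))[1]]))
  }
  n_drop <- sum(hits$evalue >= evalue_cutoff)
  if (n_drop > 0) {
    inform(sprintf("read_domtbl: dropped %d domain hit(s) with e-value >= %g",
                   n_drop, evalue_cutoff))
  }
  hits |> filter(.data$evalue < evalue_cutoff)
}

#' Read a protein FASTA into a protein table
#'
#' Sequence parsing is delegated to [Biostrings::readAAStringSet()]. The
#' protein id is the first header token; the owning gene is taken from a
#' `gene=<id>` header field (the convention the fixture generator writes) and
#' falls back to the protein id when absent. A trailing stop symbol `*` is
#' stripped before lengths are computed, so reported lengths are amino acids
#' of the mature translation.
#'
#' @param path path to a protein FASTA file.
#' @return a tibble with `protein_id`, `gene_id`, `length`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  header <- names(aa)
  seqs <- unname(sub("\\*$", "", as.character(aa)))
  gene <- stringr::str_match(header, "gene=(\\S+)")[, 2]
  pid <- stringr::str_extract(header, "^\\S+")
  tibble(
    protein_id = pid,
    gene_id = dplyr::coalesce(gene, pid),
    length = nchar(seqs),
    sequence = unname(seqs)
  )
}

#' Longest isoform of one gene
#'
#' When a gene has several isoforms, screens use the single isoform with the
#' longest protein. Ties on length are broken by the lexicographically
#' smallest protein id so results are deterministic.
#'
#' @param gene_id a single gene id.
#' @param proteins a protein table (`protein_id`, `gene_id`, `length`).
#' @return the selected one-row protein tibble.
#' @export
longest_isoform <- function(gene_id, proteins) {
  assert_cols(proteins, c("protein_id", "gene_id", "length"), "protein table")
  sub <- proteins[proteins$gene_id == gene_id, ]
  if (nrow(sub) == 0) {
    abort(paste0("no translation found for gene ", gene_id))
  }
  sub |>
    arrange(dplyr::desc(.data$length), .data$protein_id) |>
    slice(1)
}

#' Longest isoform per gene, for a whole proteome
#'
#' @param proteins a protein table.
#' @return one row per gene, same columns as the input.
#' @export
longest_isoforms <- function(proteins) {
  assert_cols(proteins, c("protein_id", "gene_id", "length"), "protein table")
  proteins |>
    arrange(dplyr::desc(.data$length), .data$protein_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup()
}

#' Read a one-to-one ortholog pair table
#'
#' @param path TSV with header columns `focal_gene`, `reference_gene`.
#' @return a tibble of pairs.
#' @export
read_ortholog_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  assert_cols(tab, c("focal_gene", "reference_gene"), "ortholog table")
  tab
}

#' Read a curation action table
#'
#' @param path TSV with header columns `gene_id`, `action`
#'   (`keep`/`remove`/`replace`), `replacement_transcripts` (comma-separated
#'   ids, empty unless `replace`) and `provenance`.
#' @return a tibble of actions.
#' @export
read_curation_actions <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  assert_cols(tab, c("gene_id", "action"), "curation action table")
  if (!"replacement_transcripts" %in% names(tab)) {
    tab$replacement_transcripts <- NA_character_
  }
  if (!"provenance" %in% names(tab)) tab$provenance <- NA_character_
  tab
}

#' Read strand-tagged expression coverage (BED6)
#'
#' BED input is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention on read. The BED score column carries mean
#' read depth for the interval.
#'
#' @param path path to a BED6 file (`chrom start end name depth strand`).
#' @return a tibble with `seqid`, `start`, `end`, `strand`, `depth`.
#' @export
read_coverage_bed <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_names = c("seqid", "bed_start", "bed_end", "name", "depth", "strand"),
    col_types = "ciicdc", progress = FALSE)
  assert_strand(tab$strand, "coverage strand")
  if (any(tab$depth < 0)) abort("negative coverage depth")
  tab |>
    mutate(start = .data$bed_start + 1L, end = .data$bed_end) |>
    select("seqid", "start", "end", "strand", "depth")
}
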