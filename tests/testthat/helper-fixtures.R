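# Shared fixture builders; everything is generated in code at test time.

toy_gff3_lines <- function() {
  c("##gff-version 3",
    "chrI\ttoy\tgene\t101\t500\t.\t+\t.\tID=g1",
    "chrI\ttoy\tmRNA\t101\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrI\ttoy\texon\t101\t200\t.\t+\t.\tParent=g1.t1",
    "chrI\ttoy\texon\t301\t500\t.\t+\t.\tParent=g1.t1",
    "chrI\ttoy\tCDS\t151\t200\t.\t+\t0\tParent=g1.t1",
    "chrI\ttoy\tCDS\t301\t430\t.\t+\t1\tParent=g1.t1")
}

write_toy_gff3 <- function(lines = toy_gff3_lines()) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# host gene (+ strand, with 5'/3' UTRs) plus configurable companions,
# built directly as a feature table
host_features <- function() {
  tibble::tibble(
    seqid = "chrI",
    start = c(1001L, 2001L, 1051L, 2001L, 1001L, 2201L),
    end   = c(1500L, 2300L, 1500L, 2200L, 1050L, 2300L),
    strand = "+",
    type = c("exon", "exon", "cds", "cds", "utr5", "utr3"),
    transcript_id = "host.t1",
    gene_id = "host")
}

single_exon_gene <- function(gene_id, seqid, start, end, strand) {
  tibble::tibble(
    seqid = seqid, start = start, end = end, strand = strand,
    type = c("exon", "cds"),
    transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id)
}

# domain-hit table from a named list protein -> family vector
hits_from_families <- function(families_by_protein, evalue = 1e-6) {
  purrr::imap(families_by_protein, function(fams, p) {
    tibble::tibble(protein_id = p, domain_family = fams, evalue = evalue,
                   env_start = 1L, env_end = 40L)
  }) |> dplyr::bind_rows()
}

# the default planted-defect study bundle, built once per test run
defect_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fixture_config(
        n_genes = 200, n_fusions = 5, n_antisense_cds_ssogs = 5,
        n_antisense_utr_ssogs = 3, n_atypical_combinations = 4,
        n_family_outliers = 4, seed = 20201012)
      cache <<- simulate_annotation(cfg)
    }
    cache
  }
})

bundle_set_roles <- function(bundle) {
  cfg <- bundle$config
  setNames(c(rep("homology", length(cfg$homology_sets)), "orf_support"),
           c(cfg$homology_sets, cfg$orf_set))
}

protein_to_gene <- function(bundle, protein_ids) {
  unique(bundle$proteins$gene_id[match(protein_ids,
                                       bundle$proteins$protein_id)])
}
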