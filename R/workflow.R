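# End-to-end workflow: a YAML run configuration naming the input files, a
# screening pass that writes all candidate tables, and a curation pass that
# rewrites the annotation and recomputes statistics. The command-line entry
# point (inst/scripts/annocure) is a thin wrapper over these functions.

#' Read a run configuration
#'
#' The YAML layout:
#' \preformatted{
#' annotation: path.gff3
#' evidence: path.gff3            # optional, needed for replace actions
#' proteins: path.fasta
#' reference_proteins: path.fasta # optional, for the length screen
#' orthologs: path.tsv            # optional
#' domains:                       # optional; 'focal' plus reference species
#'   focal: domains_focal.domtbl
#'   speciesA: domains_speciesA.domtbl
#' blast:                         # optional; role per subject set
#'   refset1: {path: blast_refset1.tsv, role: homology}
#'   focal_orfs: {path: blast_focal_orfs.tsv, role: orf_support}
#' coverage: coverage.bed         # optional
#' actions: actions.tsv           # for the curation pass
#' out_dir: results
#' params:                        # all optional, defaults shown
#'   length_cutoff: 2.0
#'   strict_greater: false
#'   max_combination_count: 10
#'   combination_mode: pairs
#'   family_accessions: []        # screened family accessions
#'   min_family_members: 10
#'   evalue_cutoff: 0.001
#'   expression_fraction: 0.5
#' }
#'
#' @param path YAML file path.
#' @return a `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(length_cutoff = 2, strict_greater = FALSE,
                   max_combination_count = 10, combination_mode = "pairs",
                   family_accessions = character(), min_family_members = 10,
                   evalue_cutoff = 0.001, expression_fraction = 0.5)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  for (f in c("annotation", "evidence", "proteins", "reference_proteins",
              "orthologs", "coverage", "actions")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0("configured ", f, " file does not exist: ", cfg[[f]]))
    }
  }
  structure(cfg, class = "run_config")
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run all configured screens and write candidate reports
#'
#' Runs whichever screens the configuration provides inputs for (ortholog
#' length, atypical domain combinations, family length outliers, SSOG
#' calling/classification), writes one TSV per screen plus a machine-readable
#' JSON summary, the gene-level candidate union with per-screen provenance
#' flags, and the between-screen overlap report. All outputs are sorted, so
#' identical inputs give byte-identical files.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, a list with every screen result and the union table.
#' @export
screen_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- config$params
  results <- list()
  candidate_sets <- list()

  proteins <- read_protein_fasta(config$proteins)

  if (!is.null(config$orthologs) && !is.null(config$reference_proteins)) {
    pairs <- build_ortholog_pairs(read_ortholog_table(config$orthologs),
                                  proteins,
                                  read_protein_fasta(config$reference_proteins))
    ls <- screen_length_outliers(pairs, cutoff = pars$length_cutoff,
                                 strict = pars$strict_greater)
    readr::write_tsv(tidy(ls), file.path(out_dir, "length_candidates.tsv"),
                     progress = FALSE)
    write_json(as.list(glance(ls)),
               file.path(out_dir, "length_summary.json"))
    results$length_screen <- ls
    candidate_sets$ortholog_length <- tidy(ls)$focal_gene
  }

  if (!is.null(config$domains)) {
    if (is.null(config$domains$focal)) {
      abort("domains config requires a 'focal' entry")
    }
    arch <- lapply(config$domains, function(p) {
      build_architectures(read_domtbl(p, pars$evalue_cutoff))
    })
    ref_census <- lapply(arch[names(arch) != "focal"], combination_census,
                         mode = pars$combination_mode)
    cs <- screen_atypical_combinations(
      arch$focal, ref_census, max_count = pars$max_combination_count,
      mode = pars$combination_mode)
    readr::write_tsv(tidy(cs),
                     file.path(out_dir, "combination_candidates.tsv"),
                     progress = FALSE)
    results$combination_screen <- cs
    prot2gene <- setNames(proteins$gene_id, proteins$protein_id)
    candidate_sets$atypical_combination <-
      unique(unname(prot2gene[tidy(cs)$protein_id]))

    if (length(pars$family_accessions) > 0) {
      fam <- assign_families(arch$focal, longest_isoforms(proteins),
                             pars$family_accessions)
      fs <- screen_family_length_outliers(fam, pars$min_family_members)
      readr::write_tsv(tidy(fs),
                       file.path(out_dir, "family_candidates.tsv"),
                       progress = FALSE)
      results$family_screen <- fs
      candidate_sets$family_length <-
        unique(unname(prot2gene[tidy(fs)$protein_id]))
    }
  }

  if (!is.null(config$blast)) {
    set_roles <- vapply(config$blast, function(x) x$role, "")
    hits <- purrr::imap(config$blast, function(x, nm) {
      read_blast_tab(x$path, nm)
    }) |> bind_rows()
    ssogs <- call_ssogs(proteins, hits, set_roles, pars$evalue_cutoff)
    ann <- read_gff3(config$annotation)
    coverage <- if (!is.null(config$coverage)) {
      read_coverage_bed(config$coverage)
    } else NULL
    classified <- classify_ssogs(ssogs |> filter(.data$is_ssog), ann,
                                 coverage, pars$expression_fraction)
    readr::write_tsv(classified,
                     file.path(out_dir, "ssog_classification.tsv"),
                     progress = FALSE)
    summ <- ssog_category_summary(classified)
    summ_list <- if (nrow(summ) == 0) list() else {
      setNames(lapply(seq_len(nrow(summ)), function(i) {
        list(n = summ$n[i], percent = summ$percent[i])
      }), summ$category)
    }
    write_json(summ_list, file.path(out_dir, "ssog_summary.json"))
    actions <- ssog_removal_policy(classified)
    readr::write_tsv(actions, file.path(out_dir, "ssog_actions.tsv"),
                     progress = FALSE)
    results$ssog_classification <- classified
    results$ssog_actions <- actions
    candidate_sets$ssog <- classified$gene_id[classified$category !=
                                                "supported"]
  }

  union_tbl <- tibble(gene_id = sort(unique(unlist(candidate_sets))))
  for (nm in names(candidate_sets)) {
    union_tbl[[nm]] <- union_tbl$gene_id %in% candidate_sets[[nm]]
  }
  readr::write_tsv(union_tbl, file.path(out_dir, "union_candidates.tsv"),
                   progress = FALSE)
  results$union <- union_tbl

  if (length(candidate_sets) >= 2) {
    rep <- screen_overlap_report(candidate_sets)
    readr::write_tsv(rep$patterns,
                     file.path(out_dir, "overlap_patterns.tsv"),
                     progress = FALSE)
    readr::write_tsv(rep$per_screen,
                     file.path(out_dir, "overlap_per_screen.tsv"),
                     progress = FALSE)
    results$overlap <- rep
  }
  write_json(
    list(n_union_candidates = nrow(union_tbl),
         per_screen = lapply(candidate_sets, length)),
    file.path(out_dir, "screen_summary.json"))
  invisible(results)
}

#' Derive protein lengths from annotated CDS
#'
#' One protein per transcript, its length the transcript's total CDS length
#' in codons. Used to re-screen an annotation after curation, when promoted
#' transcripts have no FASTA translation yet.
#'
#' @param ann an [annotation_set()].
#' @return a protein table (`protein_id`, `gene_id`, `length`).
#' @export
proteins_from_annotation <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  ann$features |>
    filter(.data$type == "cds") |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(length = sum(.data$end - .data$start + 1L) %/% 3L,
              .groups = "drop") |>
    mutate(protein_id = paste0(.data$transcript_id, ".p")) |>
    select("protein_id", "gene_id", "length")
}

#' Apply a curation action table and write the corrected annotation
#'
#' Applies the configured actions ([apply_curation_actions()]), writes the
#' corrected GFF3 and before/after annotation statistics, and -- when an
#' ortholog table is configured -- re-runs the length screen on CDS-derived
#' protein lengths to quantify how far the candidate count went down.
#'
#' @param config a `run_config` (or path to one) with an `actions` entry.
#' @return invisibly, a list with the curated annotation, the stats table
#'   and (possibly) the rescreen delta table.
#' @export
run_curation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$actions)) abort("curation requires an actions table")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- read_gff3(config$annotation)
  actions <- read_curation_actions(config$actions)
  evidence <- if (!is.null(config$evidence)) read_gff3(config$evidence)
  curated <- apply_curation_actions(ann, actions, evidence)
  write_gff3(curated, file.path(out_dir, "curated.gff3"))

  stats <- bind_rows(
    annotation_stats(ann) |> mutate(stage = "before"),
    annotation_stats(curated) |> mutate(stage = "after"))
  readr::write_tsv(stats, file.path(out_dir, "annotation_stats.tsv"),
                   progress = FALSE)
  write_json(split(stats, stats$stage),
             file.path(out_dir, "annotation_stats.json"))
  out <- list(curated = curated, stats = stats)

  if (!is.null(config$orthologs) && !is.null(config$reference_proteins)) {
    pars <- config$params
    ortho <- read_ortholog_table(config$orthologs)
    ref <- read_protein_fasta(config$reference_proteins)
    count_candidates <- function(a) {
      pr <- proteins_from_annotation(a)
      tab <- ortho |> filter(.data$focal_gene %in% pr$gene_id)
      pairs <- build_ortholog_pairs(tab, pr, ref)
      nrow(tidy(screen_length_outliers(pairs,
                                       cutoff = pars$length_cutoff,
                                       strict = pars$strict_greater,
                                       compute_correlation = FALSE)))
    }
    delta <- rescreen_delta(c(ortholog_length = count_candidates(ann)),
                            c(ortholog_length = count_candidates(curated)))
    readr::write_tsv(delta, file.path(out_dir, "rescreen_delta.tsv"),
                     progress = FALSE)
    out$rescreen <- delta
  }
  invisible(out)
}
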