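#' Call species-specific orphan genes (SSOGs) from BLASTP evidence
#'
#' A focal gene is an SSOG when none of its proteins has a BLASTP hit below
#' the e-value cutoff in any reference set designated as homology evidence.
#' Independently, a hit below the cutoff in a set designated as focal
#' transcriptome ORFs marks the gene as having transcriptomic (ORF) support.
#'
#' @param proteins focal protein table (`protein_id`, `gene_id`).
#' @param blast_hits tibble of hits from [read_blast_tab()], tagged with
#'   `subject_set`.
#' @param set_roles named character vector mapping every `subject_set` label
#'   to `"homology"` or `"orf_support"`.
#' @param evalue_cutoff hits with `evalue < evalue_cutoff` count as evidence.
#'   Default 0.001.
#' @return a tibble with one row per focal gene: `gene_id`, `is_ssog`,
#'   `has_orf_support`.
#' @export
call_ssogs <- function(proteins, blast_hits, set_roles,
                       evalue_cutoff = 0.001) {
  assert_cols(proteins, c("protein_id", "gene_id"), "protein table")
  assert_cols(blast_hits, c("query_id", "subject_set", "evalue"),
              "BLAST hit table")
  if (is.null(names(set_roles)) || !all(set_roles %in% c("homology",
                                                         "orf_support"))) {
    abort("set_roles must be a named vector of 'homology'/'orf_support'")
  }
  unknown <- setdiff(unique(blast_hits$subject_set), names(set_roles))
  if (length(unknown) > 0) {
    abort(paste0("BLAST hits with unknown subject_set tag(s): ",
                 paste(unknown, collapse = ", ")))
  }
  sig <- blast_hits |>
    filter(.data$evalue < evalue_cutoff) |>
    mutate(role = unname(set_roles[.data$subject_set])) |>
    left_join(proteins |> select("protein_id", "gene_id"),
              by = c(query_id = "protein_id"))
  homology_genes <- unique(sig$gene_id[sig$role == "homology"])
  orf_genes <- unique(sig$gene_id[sig$role == "orf_support"])
  proteins |>
    distinct(.data$gene_id) |>
    mutate(is_ssog = !.data$gene_id %in% homology_genes,
           has_orf_support = .data$gene_id %in% orf_genes) |>
    arrange(.data$gene_id)
}

#' Classify unsupported SSOGs by strand-aware overlap and expression
#'
#' Assigns every SSOG one category by priority:
#' \describe{
#'   \item{supported}{the gene has ORF support (transcriptomic evidence).}
#'   \item{antisense_cds}{an SSOG exon overlaps >= 1 bp of another gene's CDS
#'     on the opposite strand -- the classic spurious antisense prediction.}
#'   \item{antisense_utr}{overlaps >= 1 bp of another gene's UTR on the
#'     opposite strand, with no antisense CDS overlap.}
#'   \item{other}{overlaps another gene's exons on the same strand; such
#'     entangled models are not classified further.}
#'   \item{some_expression}{same-strand read coverage (depth > 0) over at
#'     least `expression_fraction` of the SSOG's exonic bases -- some
#'     transcriptional activity, though not structure-confirming.}
#'   \item{no_support}{none of the above.}
#' }
#' Antisense categories record the overlapped sense gene with the largest
#' overlap as `triggering_gene`.
#'
#' @param ssogs tibble from [call_ssogs()], restricted to rows with
#'   `is_ssog = TRUE` (other rows are an error).
#' @param annotation the [annotation_set()] the SSOGs live in.
#' @param coverage optional strand-tagged coverage tibble
#'   ([read_coverage_bed()]).
#' @param expression_fraction exonic-base fraction needed for
#'   `some_expression`. Default 0.5.
#' @return the input tibble with `category` and `triggering_gene` columns.
#' @export
classify_ssogs <- function(ssogs, annotation, coverage = NULL,
                           expression_fraction = 0.5) {
  assert_cols(ssogs, c("gene_id", "is_ssog", "has_orf_support"),
              "SSOG table")
  if (any(!ssogs$is_ssog)) {
    abort("classify_ssogs expects SSOG records only (is_ssog = TRUE)")
  }
  stopifnot(inherits(annotation, "annotation_set"))

  ssog_ids <- ssogs$gene_id
  ex <- feature_ranges(annotation, "exon")
  ssog_ex <- ex[ex$gene_id %in% ssog_ids]
  targets <- feature_ranges(annotation, c("cds", "utr5", "utr3", "exon"))

  ov <- GenomicRanges::findOverlaps(ssog_ex, targets, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  ovl <- tibble(
    ssog_gene = ssog_ex$gene_id[q],
    other_gene = targets$gene_id[s],
    same_strand = as.character(GenomicRanges::strand(ssog_ex))[q] ==
      as.character(GenomicRanges::strand(targets))[s],
    target_type = targets$type[s],
    width = IRanges::width(IRanges::pintersect(
      IRanges::ranges(ssog_ex)[q], IRanges::ranges(targets)[s]))
  ) |>
    filter(.data$ssog_gene != .data$other_gene) |>
    mutate(kind = dplyr::case_when(
      !.data$same_strand & .data$target_type == "cds" ~ "antisense_cds",
      !.data$same_strand & .data$target_type %in% c("utr5", "utr3") ~
        "antisense_utr",
      .data$same_strand & .data$target_type == "exon" ~ "other",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$kind)) |>
    group_by(.data$ssog_gene, .data$kind, .data$other_gene) |>
    summarise(width = sum(.data$width), .groups = "drop")

  pick <- function(gene, kind_wanted) {
    hit <- ovl |>
      filter(.data$ssog_gene == gene, .data$kind == kind_wanted) |>
      arrange(dplyr::desc(.data$width), .data$other_gene)
    if (nrow(hit) == 0) NA_character_ else hit$other_gene[1]
  }

  expressed <- expressed_fraction(ssog_ids, annotation, coverage)

  classified <- ssogs |>
    mutate(
      trig_cds = purrr::map_chr(.data$gene_id, pick, "antisense_cds"),
      trig_utr = purrr::map_chr(.data$gene_id, pick, "antisense_utr"),
      trig_same = purrr::map_chr(.data$gene_id, pick, "other"),
      expr_frac = expressed[.data$gene_id],
      category = dplyr::case_when(
        has_orf_support ~ "supported",
        !is.na(trig_cds) ~ "antisense_cds",
        !is.na(trig_utr) ~ "antisense_utr",
        !is.na(trig_same) ~ "other",
        expr_frac >= expression_fraction ~ "some_expression",
        TRUE ~ "no_support"),
      triggering_gene = dplyr::case_when(
        category == "antisense_cds" ~ trig_cds,
        category == "antisense_utr" ~ trig_utr,
        category == "other" ~ trig_same,
        TRUE ~ NA_character_)
    ) |>
    select(-"trig_cds", -"trig_utr", -"trig_same")
  classified
}

# fraction of each gene's exonic bases covered (depth > 0) on its own strand
expressed_fraction <- function(gene_ids, annotation, coverage) {
  out <- setNames(rep(0, length(gene_ids)), gene_ids)
  if (length(gene_ids) == 0) return(out)
  ex <- feature_ranges(annotation, "exon")
  ex <- ex[ex$gene_id %in% gene_ids]
  ex_by_gene <- GenomicRanges::reduce(S4Vectors::split(ex, ex$gene_id))
  if (is.null(coverage) || nrow(coverage) == 0) {
    return(out)
  }
  cov <- coverage |> filter(.data$depth > 0)
  if (nrow(cov) == 0) return(out)
  cov_gr <- GenomicRanges::GRanges(cov$seqid,
                                   IRanges::IRanges(cov$start, cov$end),
                                   strand = cov$strand)
  for (g in names(ex_by_gene)) {
    exu <- ex_by_gene[[g]]
    inter <- GenomicRanges::intersect(exu, cov_gr, ignore.strand = FALSE)
    out[g] <- sum(IRanges::width(inter)) / sum(IRanges::width(exu))
  }
  out
}

#' Propose curation actions for classified SSOGs
#'
#' The default policy mirrors how unsupported orphan models are handled in
#' practice: remove categories lacking any transcriptional or structural
#' support (`no_support`, `antisense_cds`, `antisense_utr`); keep genes with
#' some expression, ORF support, or entanglement with same-strand models.
#'
#' @param classified output of [classify_ssogs()].
#' @param policy named character vector mapping each category to `"keep"` or
#'   `"remove"`.
#' @return a curation action tibble (`gene_id`, `action`,
#'   `replacement_transcripts`, `provenance`) consumable by
#'   [apply_curation_actions()].
#' @export
ssog_removal_policy <- function(
    classified,
    policy = c(no_support = "remove", antisense_cds = "remove",
               antisense_utr = "remove", some_expression = "keep",
               supported = "keep", other = "keep")) {
  assert_cols(classified, c("gene_id", "category"), "classified SSOG table")
  unknown <- setdiff(unique(classified$category), names(policy))
  if (length(unknown) > 0) {
    abort(paste0("no policy for categor(ies): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(policy %in% c("keep", "remove"))) {
    abort("policy values must be 'keep' or 'remove'")
  }
  classified |>
    mutate(action = unname(policy[.data$category]),
           replacement_transcripts = NA_character_,
           provenance = paste0("ssog_screen:", .data$category)) |>
    select("gene_id", "action", "replacement_transcripts", "provenance")
}

#' Summarise SSOG categories
#'
#' @param classified output of [classify_ssogs()].
#' @return a tibble with `category`, `n` and integer `percent` (of all input
#'   records, rounded half away from zero); empty input gives an empty
#'   tibble.
#' @export
#' @examples
#' ssog_category_summary(tibble::tibble(
#'   gene_id = as.character(1:4),
#'   category = c("antisense_cds", "antisense_cds", "no_support", "other")))
ssog_category_summary <- function(classified) {
  assert_cols(classified, c("gene_id", "category"), "classified SSOG table")
  if (nrow(classified) == 0) {
    return(tibble(category = character(), n = integer(),
                  percent = numeric()))
  }
  order_levels <- c("supported", "no_support", "some_expression",
                    "antisense_cds", "antisense_utr", "other")
  classified |>
    count(.data$category) |>
    mutate(percent = percent_of(.data$n, nrow(classified))) |>
    arrange(match(.data$category, order_levels))
}

#' Bar chart of SSOG classification categories
#'
#' @param summary output of [ssog_category_summary()].
#' @return a ggplot object.
#' @export
plot_ssog_categories <- function(summary) {
  assert_cols(summary, c("category", "n", "percent"), "category summary")
  ggplot2::ggplot(summary,
                  ggplot2::aes(stats::reorder(.data$category, .data$n),
                               .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%d%%)", .data$n,
                                                    .data$percent)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0, .2))) +
    ggplot2::labs(x = NULL, y = "SSOGs",
                  title = "Classification of species-specific orphan genes") +
    ggplot2::theme_minimal()
}
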