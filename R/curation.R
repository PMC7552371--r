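#' Apply curation actions to an annotation
#'
#' Executes keep / remove / replace-with-transcripts decisions in bulk.
#' Removed genes disappear. A replaced gene disappears and every replacement
#' transcript (taken from the `evidence` annotation, typically assembled
#' RNA-seq transcripts) is promoted to a new single-transcript gene with the
#' deterministic id `<old_gene_id>.split<N>`, so a fused model replaced by
#' its two underlying transcripts yields two genes. All other genes pass
#' through unchanged.
#'
#' Duplicate actions for one gene, actions naming unknown genes, and
#' replacement transcript ids absent from the evidence set are hard errors.
#' Promoted genes may overlap retained neighbours; a same-strand span overlap
#' only triggers a warning.
#'
#' @param annotation the [annotation_set()] to curate.
#' @param actions action tibble (`gene_id`, `action`,
#'   `replacement_transcripts` as comma-separated ids, `provenance`), e.g.
#'   from [read_curation_actions()] or [ssog_removal_policy()].
#' @param evidence [annotation_set()] holding replacement transcripts.
#' @param version_label label for the curated set; defaults to the input
#'   label with `"-curated"` appended.
#' @return a new [annotation_set()].
#' @export
apply_curation_actions <- function(annotation, actions, evidence = NULL,
                                   version_label = NULL) {
  stopifnot(inherits(annotation, "annotation_set"))
  assert_cols(actions, c("gene_id", "action"), "action table")
  if (!"replacement_transcripts" %in% names(actions)) {
    actions$replacement_transcripts <- NA_character_
  }
  if (anyDuplicated(actions$gene_id)) {
    abort(paste0("duplicate actions for gene(s): ",
                 paste(unique(actions$gene_id[duplicated(actions$gene_id)]),
                       collapse = ", ")))
  }
  bad_action <- setdiff(unique(actions$action), c("keep", "remove", "replace"))
  if (length(bad_action) > 0) {
    abort(paste0("unknown action(s): ", paste(bad_action, collapse = ", ")))
  }
  all_genes <- unique(annotation$features$gene_id)
  unknown <- setdiff(actions$gene_id, all_genes)
  if (length(unknown) > 0) {
    abort(paste0("action(s) reference unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }

  remove_ids <- actions$gene_id[actions$action == "remove"]
  repl <- actions |> filter(.data$action == "replace")
  repl_tx <- lapply(repl$replacement_transcripts, function(x) {
    ids <- if (is.na(x)) character() else trimws(strsplit(x, ",")[[1]])
    ids[nzchar(ids)]
  })
  if (nrow(repl) > 0) {
    if (any(lengths(repl_tx) == 0)) {
      abort(paste0("replace action without replacement transcripts for: ",
                   paste(repl$gene_id[lengths(repl_tx) == 0],
                         collapse = ", ")))
    }
    if (is.null(evidence)) {
      abort("replace actions require an evidence annotation")
    }
    stopifnot(inherits(evidence, "annotation_set"))
    ev_tx <- unique(evidence$features$transcript_id)
    dangling <- setdiff(unlist(repl_tx), ev_tx)
    if (length(dangling) > 0) {
      abort(paste0("replacement transcript(s) not in evidence set: ",
                   paste(dangling, collapse = ", ")))
    }
  }

  kept <- annotation$features |>
    filter(!.data$gene_id %in% c(remove_ids, repl$gene_id))

  promoted <- purrr::map2(repl$gene_id, repl_tx, function(g, txs) {
    purrr::imap(txs, function(tx, i) {
      evidence$features |>
        filter(.data$transcript_id == tx) |>
        mutate(gene_id = paste0(g, ".split", i))
    }) |> bind_rows()
  }) |> bind_rows()

  if (nrow(promoted) > 0) {
    per_gene <- promoted |> distinct(.data$transcript_id, .data$gene_id)
    reused <- per_gene$transcript_id[duplicated(per_gene$transcript_id)]
    clash <- c(intersect(unique(promoted$transcript_id),
                         unique(kept$transcript_id)), reused)
    if (length(clash) > 0) {
      abort(paste0("replacement transcript id(s) already present: ",
                   paste(unique(clash), collapse = ", ")))
    }
  }
  out <- annotation_set(
    bind_rows(kept, promoted),
    version_label = version_label %||%
      if (nzchar(annotation$version_label)) {
        paste0(annotation$version_label, "-curated")
      } else ""
  )
  if (nrow(promoted) > 0 && nrow(kept) > 0) {
    warn_promoted_overlaps(out, unique(promoted$gene_id))
  }
  out
}

# warn when a promoted gene's span overlaps a retained same-strand gene
warn_promoted_overlaps <- function(ann, new_ids) {
  gs <- gene_spans(ann)
  gr <- GenomicRanges::GRanges(gs$seqid, IRanges::IRanges(gs$start, gs$end),
                               strand = gs$strand, gene_id = gs$gene_id)
  new <- gr[gr$gene_id %in% new_ids]
  old <- gr[!gr$gene_id %in% new_ids]
  ov <- GenomicRanges::findOverlaps(new, old, ignore.strand = FALSE)
  if (length(ov) > 0) {
    pairs <- paste0(new$gene_id[S4Vectors::queryHits(ov)], "~",
                    old$gene_id[S4Vectors::subjectHits(ov)])
    warn(paste0("promoted gene(s) overlap retained same-strand gene(s): ",
                paste(unique(pairs), collapse = ", ")))
  }
  invisible(NULL)
}

#' Megabases of unique protein-coding sequence
#'
#' Genomic bases covered by at least one CDS interval of any transcript,
#' divided by 1e6. The union is taken over the genome (unstranded), so
#' isoforms -- and rare overlapping genes -- are never double-counted.
#'
#' @param ann an [annotation_set()].
#' @return coding megabases (double).
#' @export
coding_megabases <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  cds <- feature_ranges(ann, "cds")
  if (length(cds) == 0) return(0)
  sum(IRanges::width(GenomicRanges::reduce(cds, ignore.strand = TRUE))) / 1e6
}

#' Annotation summary statistics
#'
#' @param ann an [annotation_set()].
#' @return one-row tibble: `version_label`, `n_genes`, `n_transcripts`,
#'   `coding_mb`.
#' @export
annotation_stats <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  tibble(
    version_label = ann$version_label,
    n_genes = n_genes(ann),
    n_transcripts = dplyr::n_distinct(ann$features$transcript_id),
    coding_mb = coding_megabases(ann)
  )
}

#' Before/after comparison of screen candidate counts
#'
#' @param before,after named numeric vectors (or two-column `screen`/`count`
#'   tibbles) of per-screen candidate counts; the screen names must match.
#' @return a tibble with `screen`, `before`, `after`, `change`, `pct_change`
#'   (signed percentage of the before count) and `direction`.
#' @export
#' @examples
#' rescreen_delta(c(ortholog_length = 532), c(ortholog_length = 265))
rescreen_delta <- function(before, after) {
  as_counts <- function(x, what) {
    if (is.data.frame(x)) {
      assert_cols(x, c("screen", "count"), what)
      setNames(x$count, x$screen)
    } else {
      if (is.null(names(x))) abort(paste0(what, " must be named"))
      x
    }
  }
  b <- as_counts(before, "before counts")
  a <- as_counts(after, "after counts")
  if (!setequal(names(b), names(a))) {
    abort("before/after screen names do not match")
  }
  a <- unname(a[names(b)])
  nms <- names(b)
  b <- unname(b)
  tibble(
    screen = nms,
    before = b,
    after = a,
    change = a - b,
    pct_change = ifelse(b == 0, NA_real_, 100 * (a - b) / b),
    direction = dplyr::case_when(a < b ~ "down", a > b ~ "up",
                                 TRUE ~ "unchanged")
  )
}

#' Percentage of alignments assignable to gene annotations
#'
#' Re-implementation of feature-assignment counting at whole-alignment
#' granularity: an alignment is assigned when it overlaps at least 1 bp of
#' exon of exactly one gene. Alignments overlapping exons of two or more
#' genes are ambiguous, alignments overlapping none are unassigned; both
#' count against the percentage. Overlap is unstranded.
#'
#' @param alignments tibble of alignment intervals (`seqid`, `start`, `end`;
#'   1-based inclusive), e.g. BED-converted read alignments.
#' @param annotation an [annotation_set()].
#' @return one-row tibble: `n_alignments`, `n_assigned`, `n_ambiguous`,
#'   `n_unassigned`, `percent_assigned`.
#' @export
assign_alignments <- function(alignments, annotation) {
  assert_cols(alignments, c("seqid", "start", "end"), "alignment table")
  if (nrow(alignments) == 0) abort("no alignments to assign")
  stopifnot(inherits(annotation, "annotation_set"))
  aln <- GenomicRanges::GRanges(alignments$seqid,
                                IRanges::IRanges(alignments$start,
                                                 alignments$end))
  ex <- feature_ranges(annotation, "exon")
  ov <- GenomicRanges::findOverlaps(aln, ex, ignore.strand = TRUE)
  genes_per_aln <- tibble(
    aln = S4Vectors::queryHits(ov),
    gene = ex$gene_id[S4Vectors::subjectHits(ov)]
  ) |>
    distinct() |>
    count(.data$aln)
  n_total <- nrow(alignments)
  n_assigned <- sum(genes_per_aln$n == 1)
  n_ambiguous <- sum(genes_per_aln$n > 1)
  tibble(
    n_alignments = n_total,
    n_assigned = n_assigned,
    n_ambiguous = n_ambiguous,
    n_unassigned = n_total - n_assigned - n_ambiguous,
    percent_assigned = 100 * n_assigned / n_total
  )
}

#' Candidate overlap between screens
#'
#' For each screen, how many candidates are specific to it (found by no
#' other screen), together with the full intersection-pattern breakdown --
#' the numbers behind an upset/Venn view of complementary screens.
#'
#' @param candidate_sets named list (>= 2) of candidate gene-id vectors.
#' @return a list of class `overlap_report` with `per_screen` (screen, total,
#'   specific counts), `patterns` (membership pattern, count) and
#'   `union_size`.
#' @export
screen_overlap_report <- function(candidate_sets) {
  stopifnot(is.list(candidate_sets), length(candidate_sets) >= 2,
            !is.null(names(candidate_sets)))
  membership <- purrr::imap(candidate_sets, function(ids, nm) {
    tibble(id = unique(as.character(ids)), screen = nm)
  }) |> bind_rows()
  per_id <- membership |>
    group_by(.data$id) |>
    summarise(pattern = paste(sort(.data$screen), collapse = "+"),
              n_screens = n(), .groups = "drop")
  patterns <- per_id |> count(.data$pattern) |> arrange(.data$pattern)
  per_screen <- purrr::imap(candidate_sets, function(ids, nm) {
    ids <- unique(as.character(ids))
    spec <- per_id |> filter(.data$n_screens == 1, .data$pattern == nm)
    tibble(screen = nm, n_candidates = length(ids),
           n_specific = nrow(spec))
  }) |> bind_rows()
  structure(
    list(per_screen = per_screen, patterns = patterns,
         union_size = nrow(per_id)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: %d screens, union of %d candidates>\n",
              nrow(x$per_screen), x$union_size))
  print(x$per_screen)
  invisible(x)
}

#' @rdname screen_overlap_report
#' @param x an `overlap_report`.
#' @param ... unused.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) x$patterns

#' @rdname screen_overlap_report
#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(n_screens = nrow(x$per_screen), union_size = x$union_size)
}
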