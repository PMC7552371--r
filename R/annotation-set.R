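#' In-memory gene annotation model
#'
#' An `annotation_set` is the object every screen reads and the curation
#' engine rewrites: a flat feature table (one row per exon/CDS/UTR interval)
#' plus a version label. Coordinates follow the GFF3 convention -- 1-based,
#' inclusive, strand `+`/`-` -- everywhere in memory.
#'
#' The feature table has columns `seqid`, `start`, `end`, `strand`, `type`
#' (one of `"exon"`, `"cds"`, `"utr5"`, `"utr3"`), `transcript_id`,
#' `gene_id`. Gene and transcript spans are derived, never stored. When a
#' transcript has exons and CDS but no UTR rows, UTRs are derived as exonic
#' bases outside the CDS, split into 5'/3' by strand.
#'
#' @param features a data frame of feature intervals (see Details).
#' @param version_label free-text label carried through to statistics tables.
#' @param derive_utrs derive missing UTR intervals from exon minus CDS?
#' @return an object of class `annotation_set`.
#' @export
#' @examples
#' ann <- annotation_set(tibble::tibble(
#'   seqid = "chrI", start = c(101L, 301L, 151L, 301L),
#'   end = c(200L, 500L, 200L, 450L), strand = "+",
#'   type = c("exon", "exon", "cds", "cds"),
#'   transcript_id = "t1", gene_id = "g1"))
#' generics::glance(ann)
annotation_set <- function(features, version_label = "", derive_utrs = TRUE) {
  assert_cols(features, c("seqid", "start", "end", "strand", "type",
                          "transcript_id", "gene_id"), "feature table")
  features <- tibble::as_tibble(features) |>
    mutate(
      seqid = as.character(.data$seqid),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      type = tolower(as.character(.data$type)),
      transcript_id = as.character(.data$transcript_id),
      gene_id = as.character(.data$gene_id)
    ) |>
    select("seqid", "start", "end", "strand", "type", "transcript_id",
           "gene_id")
  ann <- structure(
    list(features = features, version_label = as.character(version_label)),
    class = "annotation_set"
  )
  ann <- validate_annotation(ann)
  if (derive_utrs) ann <- derive_utr_features(ann)
  ann
}

#' Validate annotation-set invariants
#'
#' Checks coordinate sanity, strand symbols, per-transcript consistency
#' (single seqid and strand, non-overlapping exons, CDS contained in the
#' exon union) and id uniqueness (a transcript belongs to exactly one gene).
#' Hard-errors naming the offending record.
#'
#' @param ann an `annotation_set`.
#' @return the validated object, invisibly unchanged.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  ft <- ann$features
  if (nrow(ft) == 0) return(ann)

  bad_type <- setdiff(unique(ft$type), c("exon", "cds", "utr5", "utr3"))
  if (length(bad_type) > 0) {
    abort(paste0("unknown feature type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (any(ft$start < 1L)) abort("feature start < 1 (coordinates are 1-based)")
  if (any(ft$end < ft$start)) {
    bad <- ft$transcript_id[ft$end < ft$start][1]
    abort(paste0("feature end < start in transcript ", bad))
  }
  assert_strand(ft$strand)

  multi_parent <- ft |>
    distinct(.data$transcript_id, .data$gene_id) |>
    count(.data$transcript_id) |>
    filter(n > 1)
  if (nrow(multi_parent) > 0) {
    abort(paste0("transcript linked to multiple genes: ",
                 paste(multi_parent$transcript_id, collapse = ", ")))
  }

  per_tx <- ft |>
    group_by(.data$transcript_id) |>
    summarise(
      n_seq = dplyr::n_distinct(.data$seqid),
      n_str = dplyr::n_distinct(.data$strand),
      has_exon = any(.data$type == "exon"),
      .groups = "drop"
    )
  if (any(per_tx$n_seq > 1 | per_tx$n_str > 1)) {
    bad <- per_tx$transcript_id[per_tx$n_seq > 1 | per_tx$n_str > 1][1]
    abort(paste0("transcript ", bad, " mixes sequences or strands"))
  }
  if (any(!per_tx$has_exon)) {
    bad <- per_tx$transcript_id[!per_tx$has_exon][1]
    abort(paste0("transcript ", bad, " has no exon"))
  }

  exons <- features_by_tx(ft, "exon")
  ex_red <- IRanges::reduce(exons)
  if (!all(S4Vectors::elementNROWS(exons) == S4Vectors::elementNROWS(ex_red))) {
    n1 <- S4Vectors::elementNROWS(exons); n2 <- S4Vectors::elementNROWS(ex_red)
    abort(paste0("overlapping exons within transcript ",
                 names(exons)[which(n1 != n2)[1]]))
  }
  cds <- features_by_tx(ft, "cds")
  if (length(cds) > 0) {
    common <- intersect(names(cds), names(ex_red))
    outside <- IRanges::setdiff(cds[common], ex_red[common])
    n_out <- S4Vectors::elementNROWS(outside)
    if (any(n_out > 0)) {
      abort(paste0("CDS outside exon union in transcript ",
                   names(outside)[which(n_out > 0)[1]]))
    }
  }
  ann
}

# IRangesList of one feature type, split by transcript_id
features_by_tx <- function(ft, type) {
  sub <- ft[ft$type == type, ]
  S4Vectors::splitAsList(IRanges::IRanges(sub$start, sub$end), sub$transcript_id)
}

# derive utr5/utr3 rows for transcripts that have CDS but no UTR features
derive_utr_features <- function(ann) {
  ft <- ann$features
  has_utr <- unique(ft$transcript_id[ft$type %in% c("utr5", "utr3")])
  has_cds <- unique(ft$transcript_id[ft$type == "cds"])
  todo <- setdiff(has_cds, has_utr)
  if (length(todo) == 0) return(ann)

  sub <- ft[ft$transcript_id %in% todo, ]
  exons <- features_by_tx(sub, "exon")
  cds <- features_by_tx(sub, "cds")
  utr <- IRanges::setdiff(exons[names(cds)], cds)
  n_per <- S4Vectors::elementNROWS(utr)
  if (sum(n_per) == 0) return(ann)

  flat <- unlist(utr, use.names = FALSE)
  tx <- rep(names(utr), n_per)
  meta <- sub |>
    distinct(.data$transcript_id, .data$seqid, .data$strand, .data$gene_id)
  cds_start <- min(IRanges::start(cds))[match(tx, names(cds))]
  rows <- tibble(
    transcript_id = tx,
    start = IRanges::start(flat),
    end = IRanges::end(flat)
  ) |>
    left_join(meta, by = "transcript_id") |>
    mutate(
      type = dplyr::if_else(
        xor(.data$strand == "+", .data$end >= cds_start), "utr5", "utr3")
    ) |>
    select("seqid", "start", "end", "strand", "type", "transcript_id",
           "gene_id")
  ann$features <- bind_rows(ann$features, rows)
  ann
}

#' Derived gene spans
#'
#' @param ann an `annotation_set`.
#' @return a tibble with one row per gene: `gene_id`, `seqid`, `start`,
#'   `end`, `strand`, `n_transcripts`.
#' @export
gene_spans <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  ann$features |>
    group_by(.data$gene_id) |>
    summarise(
      seqid = first(.data$seqid), start = min(.data$start),
      end = max(.data$end), strand = first(.data$strand),
      n_transcripts = dplyr::n_distinct(.data$transcript_id),
      .groups = "drop"
    ) |>
    arrange(.data$seqid, .data$start)
}

#' Derived transcript spans
#'
#' @param ann an `annotation_set`.
#' @return a tibble with one row per transcript.
#' @export
transcript_spans <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  ann$features |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(
      seqid = first(.data$seqid), start = min(.data$start),
      end = max(.data$end), strand = first(.data$strand),
      .groups = "drop"
    ) |>
    arrange(.data$seqid, .data$start)
}

#' Number of genes in an annotation set
#' @param ann an `annotation_set`.
#' @return integer count.
#' @export
n_genes <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  dplyr::n_distinct(ann$features$gene_id)
}

#' Feature intervals as a GRanges, tagged with gene and transcript ids
#'
#' @param ann an `annotation_set`.
#' @param type feature types to keep (default all).
#' @return a [GenomicRanges::GRanges] with `gene_id`, `transcript_id`, `type`
#'   metadata columns.
#' @export
feature_ranges <- function(ann, type = c("exon", "cds", "utr5", "utr3")) {
  stopifnot(inherits(ann, "annotation_set"))
  ft <- ann$features[ann$features$type %in% type, ]
  GenomicRanges::GRanges(
    seqnames = ft$seqid,
    ranges = IRanges::IRanges(ft$start, ft$end),
    strand = ft$strand,
    gene_id = ft$gene_id, transcript_id = ft$transcript_id, type = ft$type
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set%s: %d genes, %d transcripts, %d feature intervals>\n",
    if (nzchar(x$version_label)) paste0(" '", x$version_label, "'") else "",
    n_genes(x), dplyr::n_distinct(x$features$transcript_id),
    nrow(x$features)))
  invisible(x)
}

#' @rdname annotation_set
#' @param x an `annotation_set` (for `tidy`/`glance`).
#' @param ... unused.
#' @method tidy annotation_set
#' @export
tidy.annotation_set <- function(x, ...) {
  x$features |>
    arrange(.data$seqid, .data$gene_id, .data$transcript_id, .data$start,
            .data$type)
}

#' @rdname annotation_set
#' @method glance annotation_set
#' @export
glance.annotation_set <- function(x, ...) {
  tibble(
    version_label = x$version_label,
    n_genes = n_genes(x),
    n_transcripts = dplyr::n_distinct(x$features$transcript_id),
    n_feature_intervals = nrow(x$features),
    coding_mb = coding_megabases(x)
  )
}

# structural equality used by round-trip tests: canonically ordered features
#' Compare two annotation sets structurally
#'
#' @param a,b `annotation_set` objects.
#' @return TRUE if the canonicalised feature tables are identical.
#' @export
annotation_identical <- function(a, b) {
  isTRUE(all.equal(as.data.frame(tidy.annotation_set(a)),
                   as.data.frame(tidy.annotation_set(b)),
                   check.attributes = FALSE))
}
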