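#' Read a GFF3 gene annotation
#'
#' Imports gene/mRNA/exon/CDS/UTR records linked by `ID`/`Parent` attributes
#' and assembles them into an [annotation_set()]. Feature parsing (attribute
#' un-escaping, typing) is delegated to [rtracklayer::import()]; this
#' function adds the hierarchy checks. Transcripts whose `Parent` gene is
#' absent, leaf features with unknown parents, and CDS intervals outside the
#' exon union are hard errors naming the offending record. UTR features
#' missing from the file are derived as exon-minus-CDS, split 5'/3' by
#' strand.
#'
#' @param path path to a GFF3 file.
#' @param version_label label stored on the returned object.
#' @return an [annotation_set()].
#' @export
read_gff3 <- function(path, version_label = "") {
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  id <- g$ID
  parent <- g$Parent # CharacterList

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  leaf_map <- c(exon = "exon", CDS = "cds",
                five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  is_leaf <- type %in% names(leaf_map)

  gene_ids <- id[is_gene]
  if (anyNA(gene_ids)) abort("gene record without an ID attribute")

  tx_id <- id[is_tx]
  npar <- S4Vectors::elementNROWS(parent[is_tx])
  if (any(npar != 1)) {
    abort(paste0("mRNA record without exactly one Parent: ",
                 paste(tx_id[npar != 1], collapse = ", ")))
  }
  tx_parent <- unlist(parent[is_tx], use.names = FALSE)
  missing_gene <- setdiff(tx_parent, gene_ids)
  if (length(missing_gene) > 0) {
    abort(paste0("mRNA Parent gene(s) not defined in file: ",
                 paste(missing_gene, collapse = ", ")))
  }
  tx2gene <- setNames(tx_parent, tx_id)

  lf <- g[is_leaf]
  np <- S4Vectors::elementNROWS(lf$Parent)
  if (any(np == 0)) {
    abort("leaf feature (exon/CDS/UTR) without a Parent attribute")
  }
  # a leaf may list several parent transcripts; expand
  lf_rep <- rep(seq_along(lf), np)
  lf_parent <- unlist(lf$Parent, use.names = FALSE)
  unknown <- setdiff(lf_parent, tx_id)
  if (length(unknown) > 0) {
    abort(paste0("exon/CDS/UTR Parent is not an mRNA in this file: ",
                 paste(unique(unknown), collapse = ", ")))
  }

  features <- tibble(
    seqid = as.character(GenomicRanges::seqnames(lf))[lf_rep],
    start = GenomicRanges::start(lf)[lf_rep],
    end = GenomicRanges::end(lf)[lf_rep],
    strand = as.character(GenomicRanges::strand(lf))[lf_rep],
    type = unname(leaf_map[as.character(lf$type)[lf_rep]]),
    transcript_id = lf_parent,
    gene_id = unname(tx2gene[lf_parent])
  )

  orphan_genes <- setdiff(gene_ids, tx_parent)
  if (length(orphan_genes) > 0) {
    warn(paste0("dropping gene(s) without transcripts: ",
                paste(orphan_genes, collapse = ", ")))
  }
  annotation_set(features, version_label = version_label)
}

#' Write an annotation set as GFF3
#'
#' Emits a sorted, spec-conformant GFF3 (gene, mRNA, exon, CDS with computed
#' phase, five_prime_UTR/three_prime_UTR) such that
#' `read_gff3(write_gff3(a))` reproduces `a` structurally. Output is
#' deterministic: features are canonically ordered and no timestamp comments
#' are written.
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(ann$features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gs <- gene_spans(ann)
  ts <- transcript_spans(ann)
  type_out <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  leaves <- ann$features |>
    mutate(
      type = unname(type_out[.data$type]),
      ID = NA_character_, Parent = .data$transcript_id,
      phase = NA_integer_
    )
  # CDS phase: cumulative coding length 5'->3' within each transcript
  leaves <- leaves |>
    group_by(.data$transcript_id) |>
    dplyr::group_modify(function(df, key) {
      i <- which(df$type == "CDS")
      if (length(i) > 0) {
        ord <- i[order(df$start[i], decreasing = df$strand[1] == "-")]
        len <- df$end[ord] - df$start[ord] + 1L
        df$phase[ord] <- as.integer((3L - (c(0L, cumsum(len)[-length(len)]) %% 3L)) %% 3L)
      }
      df
    }) |>
    ungroup()

  rows <- bind_rows(
    gs |>
      mutate(type = "gene", ID = .data$gene_id, Parent = NA_character_,
             transcript_id = NA_character_, phase = NA_integer_),
    ts |>
      mutate(type = "mRNA", ID = .data$transcript_id, Parent = .data$gene_id,
             phase = NA_integer_),
    leaves
  ) |>
    left_join(gs |> select("gene_id", g_start = "start"), by = "gene_id") |>
    mutate(rank = match(.data$type, c("gene", "mRNA", "exon",
                                      "five_prime_UTR", "CDS",
                                      "three_prime_UTR"))) |>
    arrange(.data$seqid, .data$g_start, .data$gene_id,
            !is.na(.data$transcript_id), .data$transcript_id,
            .data$rank, .data$start, .data$end)

  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqid,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$source <- "annocure"
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- rows$phase
  S4Vectors::mcols(gr)$ID <- rows$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    ifelse(is.na(rows$Parent), list(character()), as.list(rows$Parent)))
  rtracklayer::export(gr, path, format = "gff3")
  # drop run-dependent comment lines so identical inputs give identical bytes
  lines <- readLines(path)
  keep <- !grepl("^##(source-version|date)", lines)
  writeLines(lines[keep], path)
  invisible(path)
}
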