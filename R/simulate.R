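# Synthetic fixture generator: builds an annotation with consistent
# exon/CDS/UTR structure plus the companion evidence (proteome, ortholog
# table, per-species domain hits, BLAST hits, strand-specific coverage) and
# plants known defect classes, so every screen can be exercised against a
# truth table without any external data.

#' Fixture generator configuration
#'
#' Defines the study conditions a synthetic annotation bundle emulates:
#' baseline gene structure (uniform exon counts and sizes), the proteome and
#' homology evidence, and the planted defect counts. All randomness is driven
#' by the mandatory `seed`; the same config yields byte-identical output
#' files.
#'
#' @param n_genes baseline number of genes. Default 200.
#' @param n_sequences number of (genome-less) sequences genes are laid on.
#' @param sequence_length length budget per sequence; packing beyond it is an
#'   error.
#' @param exon_count inclusive range of exons per transcript.
#' @param exon_bp,intron_bp,utr_bp,intergenic_bp inclusive size ranges (bp).
#' @param isoform_prob probability a multi-exon gene gets a second, shorter
#'   isoform.
#' @param n_fusions number of artificial gene fusions to plant.
#' @param n_antisense_cds_ssogs,n_antisense_utr_ssogs numbers of spurious
#'   antisense orphan models to plant over CDS / UTR of host genes.
#' @param n_atypical_combinations number of proteins given a domain pair
#'   absent from every reference species.
#' @param n_family_outliers number of planted length outliers in the screened
#'   gene family.
#' @param family_accession accession of the screened gene family.
#' @param n_family_members clean members of that family (protein lengths are
#'   drawn from a tight band so planted outliers are unambiguous).
#' @param reference_species labels of reference species for the domain
#'   census.
#' @param homology_sets labels of the BLAST reference sets that count as
#'   homology evidence.
#' @param orf_set label of the focal-transcriptome ORF set (counts as
#'   transcriptomic support).
#' @param seed integer seed (mandatory).
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_genes = 200, n_sequences = 5,
                           sequence_length = 2e6,
                           exon_count = c(1, 5), exon_bp = c(100, 600),
                           intron_bp = c(50, 200), utr_bp = c(30, 90),
                           intergenic_bp = c(200, 1000),
                           isoform_prob = 0.2,
                           n_fusions = 0,
                           n_antisense_cds_ssogs = 0,
                           n_antisense_utr_ssogs = 0,
                           n_atypical_combinations = 0,
                           n_family_outliers = 0,
                           family_accession = "PF01391",
                           n_family_members = 40,
                           reference_species = c("nematode_refA",
                                                 "nematode_refB",
                                                 "nematode_refC"),
                           homology_sets = c("refset1", "refset2",
                                             "refset3", "refset4"),
                           orf_set = "focal_orfs",
                           seed) {
  if (missing(seed)) abort("fixture_config requires an explicit seed")
  cfg <- list(
    n_genes = as.integer(n_genes), n_sequences = as.integer(n_sequences),
    sequence_length = sequence_length,
    exon_count = as.integer(exon_count), exon_bp = as.integer(exon_bp),
    intron_bp = as.integer(intron_bp), utr_bp = as.integer(utr_bp),
    intergenic_bp = as.integer(intergenic_bp),
    isoform_prob = isoform_prob,
    n_fusions = as.integer(n_fusions),
    n_antisense_cds_ssogs = as.integer(n_antisense_cds_ssogs),
    n_antisense_utr_ssogs = as.integer(n_antisense_utr_ssogs),
    n_atypical_combinations = as.integer(n_atypical_combinations),
    n_family_outliers = as.integer(n_family_outliers),
    family_accession = family_accession,
    n_family_members = as.integer(n_family_members),
    reference_species = reference_species,
    homology_sets = homology_sets, orf_set = orf_set,
    seed = as.integer(seed)
  )
  n_defect_genes <- 2L * cfg$n_fusions + cfg$n_antisense_cds_ssogs +
    cfg$n_antisense_utr_ssogs + cfg$n_atypical_combinations
  if (n_defect_genes + max(cfg$n_family_members, 0) > cfg$n_genes) {
    abort("defect counts plus family members exceed n_genes")
  }
  if (cfg$n_family_outliers > cfg$n_family_members) {
    abort("more family outliers than family members")
  }
  structure(cfg, class = "fixture_config")
}

# core domain vocabulary shared by the focal species and every reference
core_domain_vocab <- function() {
  c("PF00023", "PF00069", "PF00059", "PF00096", "PF00008", "PF00400")
}

sample_between <- function(range, n = 1) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

# build features + protein rows for one gene; returns list(features,
# proteins, end) . target_protein_len forces a single-exon gene of that
# coding length (used for gene-family members and planted outliers).
build_gene <- function(cfg, gid, seqid, start, strand,
                       target_protein_len = NULL) {
  u5 <- sample_between(cfg$utr_bp)
  u3 <- sample_between(cfg$utr_bp)
  if (!is.null(target_protein_len)) {
    k <- 1L
    exon_len <- u5 + 3L * target_protein_len + u3
    intron_len <- integer()
  } else {
    k <- sample_between(cfg$exon_count)
    exon_len <- sample_between(cfg$exon_bp, k)
    # terminal exons must hold the UTR plus some coding sequence
    exon_len[1] <- max(exon_len[1], u5 + 60L)
    exon_len[k] <- max(exon_len[k], u3 + 60L)
    if (k == 1) exon_len[1] <- max(exon_len[1], u5 + u3 + 90L)
    intron_len <- sample_between(cfg$intron_bp, max(k - 1L, 0L))
    if (k == 1) intron_len <- integer()
  }
  ex_start <- integer(k); ex_end <- integer(k)
  pos <- start
  for (i in seq_len(k)) {
    ex_start[i] <- pos
    ex_end[i] <- pos + exon_len[i] - 1L
    pos <- ex_end[i] + (if (i < k) intron_len[i] else 0L) + 1L
  }
  cds_start <- ex_start[1] + u5
  cds_end <- ex_end[k] - u3
  coding <- sum(pmax(0L, pmin(ex_end, cds_end) - pmax(ex_start, cds_start) + 1L))
  cds_end <- cds_end - coding %% 3L
  cds_rows <- tibble(
    start = pmax(ex_start, cds_start), end = pmin(ex_end, cds_end)
  ) |> filter(.data$end >= .data$start)
  coding <- sum(cds_rows$end - cds_rows$start + 1L)
  tid <- paste0(gid, ".t1")
  utr_rows <- tibble(
    start = c(ex_start[1], cds_end + 1L),
    end = c(cds_start - 1L, ex_end[k]),
    pos5 = c(TRUE, FALSE)
  ) |>
    filter(.data$end >= .data$start) |>
    mutate(type = dplyr::if_else(xor(strand == "+", .data$pos5),
                                 "utr3", "utr5")) |>
    select(-"pos5")
  feats <- bind_rows(
    tibble(start = ex_start, end = ex_end, type = "exon"),
    cds_rows |> mutate(type = "cds"),
    utr_rows
  ) |>
    mutate(seqid = seqid, strand = strand, transcript_id = tid,
           gene_id = gid)
  proteins <- tibble(protein_id = paste0(tid, ".p"), gene_id = gid,
                     length = coding %/% 3L)

  # optional second, shorter isoform: same exons, 3'-truncated CDS
  if (is.null(target_protein_len) && coding >= 150L &&
      runif(1) < cfg$isoform_prob) {
    m <- sample(5:15, 1)
    cds_end2 <- cds_end - 3L * m
    cds_rows2 <- tibble(
      start = pmax(ex_start, cds_start), end = pmin(ex_end, cds_end2)
    ) |> filter(.data$end >= .data$start)
    coding2 <- sum(cds_rows2$end - cds_rows2$start + 1L)
    if (coding2 >= 30L) {
      tid2 <- paste0(gid, ".t2")
      utr_rows2 <- tibble(
        start = c(ex_start[1], cds_end2 + 1L),
        end = c(cds_start - 1L, ex_end[k]),
        pos5 = c(TRUE, FALSE)
      ) |>
        filter(.data$end >= .data$start) |>
        mutate(type = dplyr::if_else(xor(strand == "+", .data$pos5),
                                     "utr3", "utr5")) |>
        select(-"pos5")
      feats2 <- bind_rows(
        tibble(start = ex_start, end = ex_end, type = "exon"),
        cds_rows2 |> mutate(type = "cds"),
        utr_rows2
      ) |>
        mutate(seqid = seqid, strand = strand, transcript_id = tid2,
               gene_id = gid)
      feats <- bind_rows(feats, feats2)
      proteins <- bind_rows(
        proteins,
        tibble(protein_id = paste0(tid2, ".p"), gene_id = gid,
               length = coding2 %/% 3L))
    }
  }
  list(features = feats, proteins = proteins, end = max(ex_end))
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Generate a synthetic annotation bundle with planted defects
#'
#' Builds non-overlapping baseline genes with consistent exon/CDS/UTR
#' structure, a matching proteome and reference evidence, then plants the
#' defect classes requested in the config: artificial fusions
#' ([plant_fusion()]), antisense orphan models ([plant_antisense_ssog()]),
#' atypical domain combinations ([plant_atypical_combination()]) and
#' gene-family length outliers. Every planted defect is listed in the truth
#' table. Identical seeds give identical bundles.
#'
#' @param config a [fixture_config()].
#' @return a `fixture_bundle` list: `annotation`, `evidence` (replacement
#'   transcripts for fused genes), `proteins`, `reference_proteins`,
#'   `ortholog_table`, `domain_hits` (named list, focal + one per reference
#'   species), `blast_hits`, `coverage`, `truth`, `suggested_actions`,
#'   `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  cfg <- config
  set.seed(cfg$seed)

  seq_of <- sort(rep_len(seq_len(cfg$n_sequences), cfg$n_genes))
  gids <- sprintf("PPA%05d", seq_len(cfg$n_genes))
  # family members (clean + planted outliers) are single-exon genes with
  # controlled protein lengths; keep them clear of other defect plants
  fam_idx <- if (cfg$n_family_members > 0) {
    sort(sample(cfg$n_genes, cfg$n_family_members))
  } else integer()
  outlier_idx <- if (cfg$n_family_outliers > 0) {
    sort(sample(fam_idx, cfg$n_family_outliers))
  } else integer()
  outlier_dir <- rep_len(c("too-long", "too-short"), length(outlier_idx))

  feats <- vector("list", cfg$n_genes)
  prots <- vector("list", cfg$n_genes)
  cursor <- rep(1L, cfg$n_sequences)
  for (i in seq_len(cfg$n_genes)) {
    s <- seq_of[i]
    seqid <- sprintf("seq%02d", s)
    start <- cursor[s] + sample_between(cfg$intergenic_bp)
    strand <- sample(c("+", "-"), 1)
    target <- NULL
    if (i %in% outlier_idx) {
      target <- if (outlier_dir[match(i, outlier_idx)] == "too-long") {
        sample(1200:1500, 1)
      } else sample(40:60, 1)
    } else if (i %in% fam_idx) {
      target <- sample(250:350, 1)
    }
    g <- build_gene(cfg, gids[i], seqid, start, strand, target)
    if (g$end > cfg$sequence_length) {
      abort("infeasible packing: genes exceed sequence_length")
    }
    cursor[s] <- g$end
    feats[[i]] <- g$features
    prots[[i]] <- g$proteins
  }
  features <- bind_rows(feats)
  proteins <- bind_rows(prots) |>
    mutate(sequence = purrr::map_chr(.data$length, random_aa))

  # domain hits: family members carry the screened family, everything else
  # one or two core families; every pairwise combination of the vocabulary
  # exists in each reference species so only planted pairs are atypical
  vocab <- core_domain_vocab()
  longest <- longest_isoforms(proteins)
  fam_gids <- gids[fam_idx]
  focal_hits <- purrr::pmap(longest, function(protein_id, gene_id, length,
                                              ...) {
    fams <- if (gene_id %in% fam_gids) {
      cfg$family_accession
    } else {
      sample(vocab, sample(1:2, 1))
    }
    tibble(protein_id = protein_id, domain_family = fams,
           evalue = 1e-10,
           env_start = 1L, env_end = as.integer(pmin(length, 50L)))
  }) |> bind_rows()

  ref_vocab <- c(vocab, cfg$family_accession)
  pair_idx <- utils::combn(length(ref_vocab), 2)
  ref_hits <- lapply(cfg$reference_species, function(sp) {
    single <- tibble(protein_id = paste0(sp, "_s", seq_along(ref_vocab)),
                     domain_family = ref_vocab)
    pairs <- tibble(
      protein_id = rep(paste0(sp, "_p", seq_len(ncol(pair_idx))), each = 2),
      domain_family = ref_vocab[as.vector(pair_idx)])
    bind_rows(single, pairs) |>
      mutate(evalue = 1e-12, env_start = 1L, env_end = 40L)
  })
  names(ref_hits) <- cfg$reference_species
  domain_hits <- c(list(focal = focal_hits), ref_hits)

  # ortholog table: every gene gets a reference counterpart of identical
  # longest-isoform length, so baseline ratios are exactly 1
  ortholog_table <- tibble(
    focal_gene = longest$gene_id,
    reference_gene = paste0("CEL_", longest$gene_id)
  )
  reference_proteins <- tibble(
    protein_id = paste0("CEL_", longest$protein_id),
    gene_id = paste0("CEL_", longest$gene_id),
    length = longest$length,
    sequence = NA_character_
  )

  # homology + ORF-support hits for every baseline protein
  blast_hits <- tidyr::crossing(
    proteins |> select("protein_id", "length"),
    subject_set = c(cfg$homology_sets, cfg$orf_set)
  ) |>
    mutate(
      query_id = .data$protein_id,
      subject_id = paste0(.data$subject_set, "|", .data$protein_id),
      pident = 85, align_length = .data$length, mismatches = 0L,
      gap_opens = 0L, query_start = 1L, query_end = .data$length,
      subject_start = 1L, subject_end = .data$length,
      evalue = 1e-50, bitscore = 300
    ) |>
    select("query_id", "subject_id", "subject_set", "pident", "align_length",
           "mismatches", "gap_opens", "query_start", "query_end",
           "subject_start", "subject_end", "evalue", "bitscore")

  bundle <- structure(list(
    annotation = annotation_set(features, version_label = "synthetic-v1"),
    evidence = annotation_set(features[0, ]),
    proteins = proteins,
    reference_proteins = reference_proteins,
    ortholog_table = ortholog_table,
    domain_hits = domain_hits,
    blast_hits = blast_hits,
    coverage = NULL,
    truth = tibble(defect = character(), gene_id = character(),
                   detail = character()),
    suggested_actions = tibble(gene_id = character(), action = character(),
                               replacement_transcripts = character(),
                               provenance = character()),
    used_genes = fam_gids,
    config = cfg
  ), class = "fixture_bundle")

  for (i in seq_len(length(outlier_idx))) {
    bundle$truth <- bind_rows(bundle$truth, tibble(
      defect = "family_outlier", gene_id = gids[outlier_idx[i]],
      detail = outlier_dir[i]))
  }

  # coverage over the exons of every baseline gene, on the gene's strand;
  # planted SSOGs added later receive none, by construction
  gs <- gene_spans(bundle$annotation)
  ex <- feature_ranges(bundle$annotation, "exon")
  ex_red <- GenomicRanges::reduce(S4Vectors::split(ex, ex$gene_id))
  cov <- purrr::map2(names(ex_red), as.list(ex_red), function(g, gr) {
    tibble(seqid = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
           strand = as.character(GenomicRanges::strand(gr)),
           depth = sample(5:50, 1))
  }) |> bind_rows()
  bundle$coverage <- cov

  for (i in seq_len(cfg$n_fusions)) bundle <- plant_fusion(bundle)
  for (i in seq_len(cfg$n_antisense_cds_ssogs)) {
    bundle <- plant_antisense_ssog(bundle, "cds")
  }
  for (i in seq_len(cfg$n_antisense_utr_ssogs)) {
    bundle <- plant_antisense_ssog(bundle, "utr")
  }
  for (i in seq_len(cfg$n_atypical_combinations)) {
    bundle <- plant_atypical_combination(bundle)
  }
  bundle
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf(
    "<fixture_bundle: %d genes, %d proteins, %d planted defect(s)>\n",
    n_genes(x$annotation), nrow(x$proteins), nrow(x$truth)))
  invisible(x)
}

# genes eligible for a new defect plant: baseline, unused, with one isoform
eligible_genes <- function(bundle) {
  one_iso <- bundle$proteins |> count(.data$gene_id) |> filter(n == 1)
  setdiff(intersect(unique(bundle$annotation$features$gene_id),
                    one_iso$gene_id),
          c(bundle$used_genes, bundle$truth$gene_id))
}

#' Plant an artificial gene fusion
#'
#' Merges two adjacent same-strand genes into a single model whose protein is
#' the concatenation of both parts. The two original transcripts are moved to
#' the evidence annotation (emulating assembled RNA-seq transcripts spanning
#' the locus), the ortholog table keeps only the first part's reference
#' ortholog -- so the fused gene's length ratio is at least two-fold and the
#' ortholog length screen must flag it -- and a replace-with-both-transcripts
#' curation action is suggested.
#'
#' @param bundle a `fixture_bundle`.
#' @param gene_pair optional character vector of two adjacent same-strand
#'   gene ids (first = upstream); chosen automatically when `NULL`, requiring
#'   the upstream part to be no longer than the downstream part.
#' @return the modified bundle.
#' @export
plant_fusion <- function(bundle, gene_pair = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  gs <- gene_spans(bundle$annotation) |> arrange(.data$seqid, .data$start)
  len_of <- setNames(longest_isoforms(bundle$proteins)$length,
                     longest_isoforms(bundle$proteins)$gene_id)
  if (is.null(gene_pair)) {
    elig <- eligible_genes(bundle)
    adj <- gs |>
      mutate(nxt = dplyr::lead(.data$gene_id),
             nxt_strand = dplyr::lead(.data$strand),
             nxt_seq = dplyr::lead(.data$seqid)) |>
      filter(.data$seqid == .data$nxt_seq, .data$strand == .data$nxt_strand,
             .data$gene_id %in% elig, .data$nxt %in% elig,
             len_of[.data$gene_id] <= len_of[.data$nxt])
    if (nrow(adj) == 0) abort("no eligible adjacent gene pair for a fusion")
    pick <- adj |> slice(sample(n(), 1))
    gene_pair <- c(pick$gene_id, pick$nxt)
  } else {
    stopifnot(length(gene_pair) == 2)
    i <- match(gene_pair, gs$gene_id)
    if (anyNA(i)) abort("gene_pair not found in annotation")
    if (abs(i[1] - i[2]) != 1 ||
        gs$seqid[i[1]] != gs$seqid[i[2]] ||
        gs$strand[i[1]] != gs$strand[i[2]]) {
      abort("gene_pair must be adjacent genes on one strand")
    }
  }
  left <- gene_pair[1]; right <- gene_pair[2]

  ft <- bundle$annotation$features
  part_feats <- ft |> filter(.data$gene_id %in% gene_pair)
  # fused model: one transcript holding both parts' exons and CDS; internal
  # former-terminal UTRs stay exon-only, as real fusion artifacts do
  strand <- part_feats$strand[1]
  left_tx <- paste0(left, ".t1"); right_tx <- paste0(right, ".t1")
  keep_utr <- if (strand == "+") c(left_tx, right_tx) else c(right_tx, left_tx)
  fused <- part_feats |>
    filter(.data$type %in% c("exon", "cds") |
             (.data$type == "utr5" & .data$transcript_id == keep_utr[1]) |
             (.data$type == "utr3" & .data$transcript_id == keep_utr[2])) |>
    mutate(transcript_id = paste0(left, ".tf1"), gene_id = left)
  bundle$annotation <- annotation_set(
    bind_rows(ft |> filter(!.data$gene_id %in% gene_pair), fused),
    version_label = bundle$annotation$version_label)

  # the two original transcripts become replacement evidence
  bundle$evidence <- annotation_set(
    bind_rows(bundle$evidence$features, part_feats),
    version_label = "evidence-transcripts")

  l1 <- unname(len_of[left]); l2 <- unname(len_of[right])
  old_prot <- bundle$proteins |> filter(.data$gene_id %in% gene_pair)
  fused_prot <- tibble(protein_id = paste0(left, ".tf1.p"), gene_id = left,
                       length = l1 + l2, sequence = random_aa(l1 + l2))
  bundle$proteins <- bind_rows(
    bundle$proteins |> filter(!.data$gene_id %in% gene_pair), fused_prot)

  bundle$ortholog_table <- bundle$ortholog_table |>
    filter(.data$focal_gene != right)

  # fused protein inherits the union of both parts' domain families
  inherited <- bundle$domain_hits$focal |>
    filter(.data$protein_id %in% old_prot$protein_id) |>
    mutate(protein_id = fused_prot$protein_id) |>
    distinct(.data$protein_id, .data$domain_family, .keep_all = TRUE)
  bundle$domain_hits$focal <- bind_rows(
    bundle$domain_hits$focal |>
      filter(!.data$protein_id %in% old_prot$protein_id),
    inherited)

  # fused protein keeps homology (it is not an orphan)
  template <- bundle$blast_hits |>
    filter(.data$query_id == old_prot$protein_id[1]) |>
    mutate(query_id = fused_prot$protein_id,
           subject_id = paste0(.data$subject_set, "|", fused_prot$protein_id),
           align_length = l1, query_end = l1, subject_end = l1)
  bundle$blast_hits <- bind_rows(
    bundle$blast_hits |> filter(!.data$query_id %in% old_prot$protein_id),
    template)

  bundle$truth <- bind_rows(bundle$truth, tibble(
    defect = "fusion", gene_id = left, detail = right))
  bundle$suggested_actions <- bind_rows(bundle$suggested_actions, tibble(
    gene_id = left, action = "replace",
    replacement_transcripts = paste(unique(part_feats$transcript_id),
                                    collapse = ","),
    provenance = "ortholog_length_screen"))
  bundle$used_genes <- c(bundle$used_genes, gene_pair)
  bundle
}

#' Plant a spurious antisense orphan gene
#'
#' Adds a single-exon, fully coding gene on the strand opposite a clean host
#' gene, overlapping the host's CDS (`kind = "cds"`) or only its UTR
#' (`kind = "utr"`). The new gene gets a protein but no BLAST hit in any
#' reference set and no coverage on its own strand, so the SSOG screen must
#' call it and classify it antisense.
#'
#' @param bundle a `fixture_bundle`.
#' @param kind `"cds"` or `"utr"`.
#' @param host optional host gene id; chosen automatically when `NULL`.
#' @return the modified bundle.
#' @export
plant_antisense_ssog <- function(bundle, kind = c("cds", "utr"),
                                 host = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  kind <- match.arg(kind)
  ft <- bundle$annotation$features
  min_w <- if (kind == "cds") 80L else 36L
  host_type <- if (kind == "cds") "cds" else c("utr5", "utr3")
  cand <- ft |>
    filter(.data$type %in% host_type,
           .data$end - .data$start + 1L >= min_w,
           .data$gene_id %in% eligible_genes(bundle))
  if (!is.null(host)) cand <- cand |> filter(.data$gene_id == host)
  if (nrow(cand) == 0) {
    abort(sprintf("no suitable host gene for an antisense %s orphan", kind))
  }
  pick <- cand |> slice(sample(n(), 1))
  w <- pick$end - pick$start + 1L
  ex_len <- min(60L, (w - 6L) %/% 3L * 3L)
  offset <- sample(0:(w - ex_len - 3L), 1)
  s <- pick$start + 3L + offset
  e <- s + ex_len - 1L
  new_strand <- if (pick$strand == "+") "-" else "+"
  idx <- sum(grepl("^SSOG", unique(ft$gene_id))) + 1L
  gid <- sprintf("SSOG%03d", idx)
  tid <- paste0(gid, ".t1")
  new_feats <- tibble(
    seqid = pick$seqid, start = s, end = e, strand = new_strand,
    type = c("exon", "cds"), transcript_id = tid, gene_id = gid)
  bundle$annotation <- annotation_set(
    bind_rows(ft, new_feats),
    version_label = bundle$annotation$version_label)
  bundle$proteins <- bind_rows(bundle$proteins, tibble(
    protein_id = paste0(tid, ".p"), gene_id = gid, length = ex_len %/% 3L,
    sequence = random_aa(ex_len %/% 3L)))
  bundle$truth <- bind_rows(bundle$truth, tibble(
    defect = paste0("antisense_", kind, "_ssog"), gene_id = gid,
    detail = pick$gene_id))
  bundle$used_genes <- c(bundle$used_genes, pick$gene_id)
  bundle
}

#' Plant an atypical domain combination
#'
#' Gives one clean focal protein two extra domain families that no reference
#' species carries; every pair they form is therefore unique to the focal
#' species and rare (one occurrence), so the combination screen must flag
#' exactly this protein.
#'
#' @param bundle a `fixture_bundle`.
#' @return the modified bundle.
#' @export
plant_atypical_combination <- function(bundle) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  elig <- eligible_genes(bundle)
  if (length(elig) == 0) abort("no eligible gene for an atypical combination")
  gid <- sample(elig, 1)
  prot <- bundle$proteins |> filter(.data$gene_id == gid) |> slice(1)
  idx <- sum(bundle$truth$defect == "atypical_combination") + 1L
  novel <- c(sprintf("PF9%03dA", idx), sprintf("PF9%03dB", idx))
  bundle$domain_hits$focal <- bind_rows(
    bundle$domain_hits$focal,
    tibble(protein_id = prot$protein_id, domain_family = novel,
           evalue = 1e-8, env_start = 1L,
           env_end = as.integer(pmin(prot$length, 40L))))
  bundle$truth <- bind_rows(bundle$truth, tibble(
    defect = "atypical_combination", gene_id = gid,
    detail = paste0(prot$protein_id, ":", paste(sort(novel),
                                                collapse = "+"))))
  bundle$used_genes <- c(bundle$used_genes, gid)
  bundle
}
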