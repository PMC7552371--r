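gene_grid <- function(n, seqid = "chrI", strand = "+") {
  purrr::map(seq_len(n), function(i) {
    s <- 1000L * i
    single_exon_gene(sprintf("g%02d", i), seqid, s, s + 299L, strand)
  }) |> dplyr::bind_rows()
}

action <- function(gene, act, repl = NA_character_) {
  tibble::tibble(gene_id = gene, action = act,
                 replacement_transcripts = repl, provenance = "test")
}

test_that("remove and replace actions rewrite the gene complement", {
  ann <- annotation_set(gene_grid(10))
  ev <- annotation_set(dplyr::bind_rows(
    single_exon_gene("evA", "chrI", 5000L, 5149L, "+"),
    single_exon_gene("evB", "chrI", 5200L, 5349L, "+")))

  removed <- apply_curation_actions(ann, action("g03", "remove"))
  expect_equal(n_genes(removed), 9)
  expect_false("g03" %in% removed$features$gene_id)

  split <- suppressWarnings(apply_curation_actions(
    ann, action("g05", "replace", "evA.t1,evB.t1"), ev))
  expect_equal(n_genes(split), 11)  # 10 - 1 + 2
  expect_setequal(setdiff(split$features$gene_id, ann$features$gene_id),
                  c("g05.split1", "g05.split2"))

  expect_error(apply_curation_actions(
    ann, dplyr::bind_rows(action("g01", "remove"), action("g01", "keep"))),
    "duplicate")
  expect_error(apply_curation_actions(ann, action("nope", "remove")),
               "unknown gene")
  expect_error(apply_curation_actions(ann, action("g01", "replace",
                                                  "ghost.t1"), ev),
               "ghost")
})

test_that("gene counts obey the conservation law on random action sets", {
  set.seed(62)
  for (rep in 1:5) {
    n <- 20
    ann <- annotation_set(gene_grid(n))
    ev_genes <- purrr::map(1:6, function(i) {
      single_exon_gene(sprintf("ev%02d", i), "chrII",
                       1000L * i, 1000L * i + 149L, "+")
    }) |> dplyr::bind_rows()
    ev <- annotation_set(ev_genes)
    gene_ids <- sprintf("g%02d", 1:n)
    r <- sample(0:4, 1); k <- sample(0:2, 1)
    chosen <- sample(gene_ids, r + k)
    sizes <- sample(1:3, k, replace = TRUE)
    # each evidence transcript can be promoted at most once
    avail <- if (k > 0) {
      split(sprintf("ev%02d.t1", seq_len(sum(sizes))),
            rep(seq_len(k), times = sizes))
    } else list()
    acts <- dplyr::bind_rows(
      if (r > 0) action(chosen[seq_len(r)], "remove"),
      if (k > 0) purrr::map(seq_len(k), function(j) {
        action(chosen[r + j], "replace", paste(avail[[j]], collapse = ","))
      }) |> dplyr::bind_rows())
    out <- if (is.null(acts) || nrow(acts) == 0) ann else
      suppressWarnings(apply_curation_actions(ann, acts, ev))
    expect_equal(n_genes(out), n - r - k + sum(sizes))
  }
})

test_that("all-keep curation is the identity", {
  ann <- annotation_set(gene_grid(8))
  out <- apply_curation_actions(
    ann, action(sprintf("g%02d", 1:8), "keep"),
    version_label = ann$version_label)
  expect_true(annotation_identical(ann, out))
})

test_that("coding megabases is a genomic union over isoforms", {
  two_iso <- tibble::tibble(
    seqid = "chrI", strand = "+",
    start = c(1L, 1L, 201L, 201L),
    end   = c(500L, 300L, 500L, 500L),
    type = c("exon", "cds", "exon", "cds"),
    transcript_id = c("g.t1", "g.t1", "g.t2", "g.t2"),
    gene_id = "g")
  ann <- annotation_set(two_iso)
  expect_equal(coding_megabases(ann), 500 / 1e6)  # union of [1,300],[201,500]

  expect_equal(coding_megabases(annotation_set(two_iso[0, ])), 0)
  expect_equal(n_genes(annotation_set(two_iso[0, ])), 0)

  grid <- annotation_set(gene_grid(50))  # 50 disjoint 300-bp CDS
  expect_equal(coding_megabases(grid), 50 * 300 / 1e6)

  # invariant under splitting one CDS into two adjacent pieces
  split_cds <- two_iso
  split_cds <- dplyr::bind_rows(
    split_cds[split_cds$type == "exon" | split_cds$transcript_id == "g.t2", ],
    tibble::tibble(seqid = "chrI", strand = "+",
                   start = c(1L, 151L), end = c(150L, 300L), type = "cds",
                   transcript_id = "g.t1", gene_id = "g"))
  expect_equal(coding_megabases(annotation_set(split_cds)),
               coding_megabases(ann))
})

test_that("rescreen deltas report signed percent changes", {
  d <- rescreen_delta(
    c(ortholog_length = 532, atypical_domains = 1589),
    c(ortholog_length = 265, atypical_domains = 1137))
  expect_equal(round(d$pct_change[d$screen == "ortholog_length"], 1), -50.2)
  expect_equal(round(d$pct_change[d$screen == "atypical_domains"], 1), -28.4)
  expect_true(all(d$direction == "down"))

  same <- rescreen_delta(c(a = 5), c(a = 5))
  expect_equal(same$change, 0)
  expect_equal(same$pct_change, 0)

  expect_error(rescreen_delta(c(a = 1), c(b = 1)), "match")
})

test_that("alignment assignment requires exactly one overlapped gene", {
  ann <- annotation_set(gene_grid(2))  # exons [1000,1299], [2000,2299]
  inside <- tibble::tibble(seqid = "chrI",
                           start = c(1010L, 1100L, 1200L),
                           end = c(1059L, 1149L, 1249L))
  expect_equal(assign_alignments(inside, ann)$percent_assigned, 100)

  spanning <- tibble::tibble(seqid = "chrI", start = 1250L, end = 2050L)
  res <- assign_alignments(spanning, ann)
  expect_equal(res$n_ambiguous, 1)
  expect_equal(res$percent_assigned, 0)

  # 50 exonic + 30 intergenic + 20 ambiguous -> 50%
  mixed <- dplyr::bind_rows(
    tibble::tibble(seqid = "chrI", start = 1000L + seq_len(50),
                   end = 1000L + seq_len(50) + 9L),
    tibble::tibble(seqid = "chrI", start = 5000L + 100L * seq_len(30),
                   end = 5000L + 100L * seq_len(30) + 9L),
    tibble::tibble(seqid = "chrI", start = rep(1290L, 20), end = 2010L))
  res <- assign_alignments(mixed, ann)
  expect_equal(res$n_assigned, 50)
  expect_equal(res$n_unassigned, 30)
  expect_equal(res$n_ambiguous, 20)
  expect_equal(res$percent_assigned, 50)

  # adding intergenic alignments strictly lowers the percentage
  worse <- dplyr::bind_rows(inside,
                            tibble::tibble(seqid = "chrI", start = 9000L,
                                           end = 9050L))
  expect_lt(assign_alignments(worse, ann)$percent_assigned, 100)

  expect_error(assign_alignments(inside[0, ], ann), "no alignments")
})

test_that("overlap report separates screen-specific candidates", {
  disjoint <- screen_overlap_report(list(a = paste0("x", 1:3),
                                         b = paste0("y", 1:5)))
  expect_equal(disjoint$per_screen$n_specific, c(3, 5))
  expect_equal(disjoint$union_size, 8)

  same <- screen_overlap_report(list(a = c("u", "v"), b = c("u", "v")))
  expect_equal(same$per_screen$n_specific, c(0, 0))

  set.seed(9)
  sets <- list(s1 = sample(letters, 10), s2 = sample(letters, 12),
               s3 = sample(letters, 8))
  rep3 <- screen_overlap_report(sets)
  # brute force: classify every id by its membership pattern
  ids <- unique(unlist(sets))
  manual <- table(vapply(ids, function(id) {
    paste(sort(names(sets)[vapply(sets, function(s) id %in% s, TRUE)]),
          collapse = "+")
  }, ""))
  got <- setNames(rep3$patterns$n, rep3$patterns$pattern)
  expect_equal(got[names(manual)], setNames(as.integer(manual),
                                            names(manual)))
})
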