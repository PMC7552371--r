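test_that("a toy GFF3 parses into the expected gene model", {
  ann <- read_gff3(write_toy_gff3())
  expect_equal(n_genes(ann), 1)
  ft <- tidy(ann)
  expect_equal(sum(ft$type == "exon"), 2)
  expect_equal(sum(ft$type == "cds"), 2)
  # UTRs derived from exon minus CDS: [101,150] 5' and [431,500] 3'
  expect_equal(ft$start[ft$type == "utr5"], 101L)
  expect_equal(ft$end[ft$type == "utr5"], 150L)
  expect_equal(ft$start[ft$type == "utr3"], 431L)
  expect_equal(ft$end[ft$type == "utr3"], 500L)
})

test_that("broken parent links and misplaced CDS are hard errors", {
  lines <- toy_gff3_lines()
  expect_error(read_gff3(write_toy_gff3(lines[lines != lines[2]])),
               "Parent gene")
  bad_cds <- c(lines, "chrI\ttoy\tCDS\t600\t650\t.\t+\t0\tParent=g1.t1")
  expect_error(read_gff3(write_toy_gff3(bad_cds)), "outside exon")
  orphan_leaf <- c(lines, "chrI\ttoy\texon\t700\t800\t.\t+\t.\tParent=ghost")
  expect_error(read_gff3(write_toy_gff3(orphan_leaf)), "ghost")
})

test_that("GFF3 writing round-trips any generated annotation", {
  cfg <- fixture_config(n_genes = 10, n_family_members = 0, seed = 11)
  ann <- simulate_annotation(cfg)$annotation
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  expect_true(annotation_identical(ann, read_gff3(path)))

  # empty set -> header-only file
  empty <- annotation_set(ann$features[0, ])
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(empty, path2)
  expect_equal(readLines(path2), "##gff-version 3")
})

test_that("negative-strand CDS phase accumulates 5' to 3'", {
  ft <- tibble::tibble(
    seqid = "chrI", strand = "-",
    start = c(101L, 301L, 101L, 301L),
    end   = c(200L, 400L, 200L, 400L),
    type = c("exon", "exon", "cds", "cds"),
    transcript_id = "m.t1", gene_id = "m")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(annotation_set(ft), path)
  cds_lines <- grep("\tCDS\t", readLines(path), value = TRUE)
  phase <- as.integer(sub(".*\t([0-2])\t[^\t]*$", "\\1",
                          sapply(strsplit(cds_lines, "\t"), `[`, 8)))
  starts <- as.integer(sapply(strsplit(cds_lines, "\t"), `[`, 4))
  # 5'-most CDS on the minus strand is the one with the larger start
  expect_equal(phase[order(-starts)],
               c(0L, (3L - (100L %% 3L)) %% 3L))
})

test_that("derived UTR bases are exonic and non-coding", {
  bundle <- defect_bundle()
  ft <- bundle$annotation$features
  for (tx in sample(unique(ft$transcript_id), 25)) {
    sub <- ft[ft$transcript_id == tx, ]
    expand <- function(t) {
      rows <- sub[sub$type %in% t, ]
      unlist(purrr::map2(rows$start, rows$end, seq))
    }
    utr <- expand(c("utr5", "utr3"))
    expect_true(all(utr %in% expand("exon")))
    expect_length(intersect(utr, expand("cds")), 0)
    expect_setequal(expand("exon"), c(utr, expand("cds")))
  }
})

test_that("domtblout parsing applies the significance cutoff at read time", {
  hits <- tibble::tibble(
    protein_id = paste0("p", 1:5),
    domain_family = paste0("PF0000", 1:5),
    evalue = c(1e-6, 0.01, 1e-4, 0.5, 0.001),
    env_start = 1L, env_end = 40L)
  path <- withr::local_tempfile(fileext = ".domtbl")
  write_domtbl(hits, path)
  expect_message(kept <- read_domtbl(path), "dropped 3")
  expect_equal(sort(kept$protein_id), c("p1", "p3"))
  expect_true(all(kept$evalue < 0.001))

  writeLines(c("# comment", "p1 - 50"), path)
  expect_error(read_domtbl(path), "truncated.*line 2")
})

test_that("BLAST tabular parsing preserves rows and flags bad e-values", {
  rows <- c(
    "q1\ts1\t90.0\t100\t10\t0\t1\t100\t1\t100\t1e-05\t200",
    "q2\ts2\t80.0\t50\t10\t1\t1\t50\t1\t50\t0.002\t90",
    "q3\ts3\t70.0\t30\t9\t2\t1\t30\t1\t30\t1.5\t40")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(rows, path)
  hits <- read_blast_tab(path, "refA")
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_id, c("q1", "q2", "q3"))
  expect_equal(hits$evalue[1], 1e-5)
  expect_true(all(hits$subject_set == "refA"))

  writeLines(character(), path)
  expect_equal(nrow(read_blast_tab(path, "refA")), 0)

  writeLines(sub("0\\.002", "abc", rows), path)
  expect_error(read_blast_tab(path, "refA"), "line 2")
})

test_that("protein FASTA reading strips stop symbols and links genes", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 gene=gA", "MKLV*", ">p2 gene=gA", "MK", ">solo", "MKV"),
             path)
  prot <- read_protein_fasta(path)
  expect_equal(prot$length, c(4L, 2L, 3L))
  expect_equal(prot$gene_id, c("gA", "gA", "solo"))
  expect_equal(prot$sequence[1], "MKLV")
})

test_that("longest-isoform selection matches a brute-force scan", {
  single <- tibble::tibble(protein_id = "lev8.p", gene_id = "lev-8",
                           length = 531L)
  expect_equal(longest_isoform("lev-8", single)$length, 531L)
  expect_error(longest_isoform("absent", single), "absent")

  ties <- tibble::tibble(protein_id = c("c", "a", "b"), gene_id = "g",
                         length = c(200L, 350L, 350L))
  pick <- longest_isoform("g", ties)
  expect_equal(pick$protein_id, "a")
  expect_equal(pick$length, 350L)

  set.seed(5)
  many <- tibble::tibble(protein_id = sprintf("p%03d", 1:100),
                         gene_id = "g", length = sample(50:2000, 100))
  best <- longest_isoform("g", many)
  # naive oracle: max scan
  expect_equal(best$length, max(many$length))
  expect_equal(best$protein_id,
               min(many$protein_id[many$length == max(many$length)]))
})
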