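two_set_roles <- c(refA = "homology", refB = "homology",
                   orfs = "orf_support")

hit_row <- function(query, set, evalue) {
  tibble::tibble(query_id = query, subject_id = paste0(set, "|x"),
                 subject_set = set, evalue = evalue)
}

test_that("SSOG calling applies the e-value cutoff per reference role", {
  prot <- tibble::tibble(protein_id = c("a.p", "b.p", "c.p"),
                         gene_id = c("a", "b", "c"))
  hits <- dplyr::bind_rows(
    hit_row("a.p", "refA", 0.01), hit_row("a.p", "refB", 0.05),
    hit_row("b.p", "refA", 1e-5),
    hit_row("c.p", "orfs", 1e-8))
  res <- call_ssogs(prot, hits, two_set_roles)
  expect_true(res$is_ssog[res$gene_id == "a"])    # hits all above cutoff
  expect_false(res$is_ssog[res$gene_id == "b"])   # real homology
  expect_true(res$is_ssog[res$gene_id == "c"])    # ORF support is not homology
  expect_true(res$has_orf_support[res$gene_id == "c"])

  expect_error(call_ssogs(prot, hit_row("a.p", "mystery", 1e-9),
                          two_set_roles), "mystery")
})

test_that("SSOG calling equals a brute-force scan on planted hits", {
  set.seed(88)
  prot <- tibble::tibble(protein_id = paste0("g", 1:20, ".p"),
                         gene_id = paste0("g", 1:20))
  hits <- purrr::map(1:60, function(i) {
    hit_row(sample(prot$protein_id, 1),
            sample(names(two_set_roles), 1),
            10^runif(1, -12, 1))
  }) |> dplyr::bind_rows()
  res <- call_ssogs(prot, hits, two_set_roles)
  oracle <- bf_ssogs(prot, hits, as.list(two_set_roles), 0.001)
  expect_equal(res$is_ssog, oracle$is_ssog)
  expect_equal(res$has_orf_support, oracle$has_orf_support)
})

test_that("relaxing the cutoff never shrinks the SSOG set", {
  set.seed(17)
  prot <- tibble::tibble(protein_id = paste0("g", 1:30, ".p"),
                         gene_id = paste0("g", 1:30))
  hits <- purrr::map(1:80, function(i) {
    hit_row(sample(prot$protein_id, 1), sample(c("refA", "refB"), 1),
            10^runif(1, -10, 0))
  }) |> dplyr::bind_rows()
  cuts <- c(1e-6, 1e-4, 1e-3, 1e-1)
  sets <- lapply(cuts, function(ct) {
    r <- call_ssogs(prot, hits, two_set_roles, evalue_cutoff = ct)
    r$gene_id[r$is_ssog]
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

ssog_record <- function(gene) {
  tibble::tibble(gene_id = gene, is_ssog = TRUE, has_orf_support = FALSE)
}

test_that("antisense overlap classification is strand- and type-aware", {
  # host gene on +: CDS [1051,2200], UTR5 [1001,1050], UTR3 [2201,2300]
  anti_cds <- single_exon_gene("ssog1", "chrI", 1101L, 1160L, "-")
  anti_utr <- single_exon_gene("ssog2", "chrI", 2210L, 2260L, "-")
  ann <- annotation_set(dplyr::bind_rows(host_features(), anti_cds, anti_utr))

  cl <- classify_ssogs(ssog_record(c("ssog1", "ssog2")), ann)
  expect_equal(cl$category[cl$gene_id == "ssog1"], "antisense_cds")
  expect_equal(cl$category[cl$gene_id == "ssog2"], "antisense_utr")
  expect_equal(unique(cl$triggering_gene), "host")

  # same categories with the host on the minus strand (strand symmetry)
  flip <- function(df) dplyr::mutate(df, strand = ifelse(strand == "+",
                                                         "-", "+"))
  ann_flip <- annotation_set(dplyr::bind_rows(
    flip(host_features()), flip(anti_cds), flip(anti_utr)))
  cl2 <- classify_ssogs(ssog_record(c("ssog1", "ssog2")), ann_flip)
  expect_equal(cl2$category, cl$category)

  # same-strand overlap cannot be antisense: it lands in "other"
  same <- single_exon_gene("ssog3", "chrI", 1101L, 1160L, "+")
  ann_same <- annotation_set(dplyr::bind_rows(host_features(), same))
  cl3 <- classify_ssogs(ssog_record("ssog3"), ann_same)
  expect_equal(cl3$category, "other")

  # CDS overlap outranks UTR overlap when one exon touches both
  both <- single_exon_gene("ssog4", "chrI", 2150L, 2250L, "-")
  ann_both <- annotation_set(dplyr::bind_rows(host_features(), both))
  expect_equal(classify_ssogs(ssog_record("ssog4"), ann_both)$category,
               "antisense_cds")

  expect_error(
    classify_ssogs(tibble::tibble(gene_id = "host", is_ssog = FALSE,
                                  has_orf_support = FALSE), ann),
    "is_ssog")
})

test_that("expression fraction separates some_expression from no_support", {
  iso <- single_exon_gene("iso1", "chrII", 5001L, 5100L, "+")  # 100 bp exon
  ann <- annotation_set(iso)

  expect_equal(classify_ssogs(ssog_record("iso1"), ann, coverage = NULL)$category,
               "no_support")

  # 60 of 100 exonic bases covered on the gene's own strand -> 0.6 >= 0.5
  cov60 <- tibble::tibble(seqid = "chrII", start = 5001L, end = 5060L,
                          strand = "+", depth = 12)
  expect_equal(classify_ssogs(ssog_record("iso1"), ann, cov60)$category,
               "some_expression")

  # same bases on the opposite strand are not support
  cov_anti <- dplyr::mutate(cov60, strand = "-")
  expect_equal(classify_ssogs(ssog_record("iso1"), ann, cov_anti)$category,
               "no_support")

  # below the configurable fraction -> no_support
  cov40 <- dplyr::mutate(cov60, end = 5040L)
  expect_equal(classify_ssogs(ssog_record("iso1"), ann, cov40)$category,
               "no_support")
  expect_equal(classify_ssogs(ssog_record("iso1"), ann, cov40,
                              expression_fraction = 0.3)$category,
               "some_expression")
})

test_that("removal policy is a per-category lookup", {
  cl <- tibble::tibble(
    gene_id = paste0("g", 1:12),
    category = rep(c("no_support", "antisense_cds", "antisense_utr",
                     "some_expression", "supported", "other"), 2))
  acts <- ssog_removal_policy(cl)
  expect_equal(nrow(acts), 12)
  lookup <- c(no_support = "remove", antisense_cds = "remove",
              antisense_utr = "remove", some_expression = "keep",
              supported = "keep", other = "keep")
  expect_equal(acts$action, unname(lookup[cl$category]))
  expect_equal(sum(acts$action == "remove"), 6)

  expect_error(ssog_removal_policy(
    tibble::tibble(gene_id = "g", category = "weird")), "weird")
})

test_that("category summary partitions records with printed-style rounding", {
  cl <- tibble::tibble(
    gene_id = sprintf("s%04d", 1:1674),
    category = rep(c("antisense_cds", "antisense_utr", "no_support",
                     "some_expression", "other"),
                   c(704, 46, 678, 196, 50)))
  summ <- ssog_category_summary(cl)
  expect_equal(sum(summ$n), 1674)
  expect_equal(summ$percent[summ$category == "antisense_cds"], 42)
  expect_equal(summ$percent[summ$category == "antisense_utr"], 3)

  empty <- ssog_category_summary(cl[0, ])
  expect_equal(nrow(empty), 0)
})
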