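hits_for <- hits_from_families

test_that("architectures deduplicate families and enumerate 2-subsets", {
  arch <- build_architectures(hits_for(list(p1 = c("A", "A", "B"))))
  expect_equal(arch$domain_family, c("A", "B"))
  expect_equal(domain_combinations(arch)$combination, "A+B")

  arch1 <- build_architectures(hits_for(list(p1 = "A")))
  expect_equal(nrow(domain_combinations(arch1)), 0)

  arch3 <- build_architectures(hits_for(list(p1 = c("A", "B", "C"))))
  expect_equal(domain_combinations(arch3)$combination,
               c("A+B", "A+C", "B+C"))  # C(3,2)

  full <- domain_combinations(arch3, mode = "full-set")
  expect_equal(full$combination, "A+B+C")
})

test_that("census counts proteins, never domain instances", {
  fams <- list(p1 = c("A", "B"), p2 = c("A", "B", "A"), p3 = c("A", "C"))
  cen <- combination_census(build_architectures(hits_for(fams)))
  expect_equal(cen$n_proteins[cen$combination == "A+B"], 2L)
  expect_equal(cen$n_proteins[cen$combination == "A+C"], 1L)
  # oracle: per-key count equals a loop over proteins
  oracle <- bf_pair_census(fams)
  for (k in names(oracle)) {
    expect_equal(cen$n_proteins[cen$combination == k], oracle[[k]],
                 info = k)
  }
})

test_that("atypical combinations require species uniqueness and rarity", {
  refs <- list(combination_census(build_architectures(
    hits_for(list(r1 = c("X", "Y"))))))

  one <- build_architectures(hits_for(list(p1 = c("A", "B"))))
  res <- screen_atypical_combinations(one, refs)
  expect_equal(tidy(res)$protein_id, "p1")
  expect_equal(tidy(res)$combination, "A+B")

  # the same pair in 12 focal proteins is an established combination
  many <- build_architectures(hits_for(
    setNames(rep(list(c("A", "B")), 12), paste0("p", 1:12))))
  expect_equal(nrow(tidy(screen_atypical_combinations(many, refs))), 0)

  # pair present in one reference species -> not unique -> not flagged
  refs_with <- list(combination_census(build_architectures(
    hits_for(list(r1 = c("A", "B"))))))
  expect_equal(nrow(tidy(screen_atypical_combinations(one, refs_with))), 0)

  bad <- combination_census(build_architectures(
    hits_for(list(r1 = c("X", "Y")))), mode = "full-set")
  expect_error(screen_atypical_combinations(one, list(bad)), "mode")
})

test_that("randomised instances match the exhaustive brute-force check", {
  set.seed(12)
  vocab <- LETTERS[1:6]
  for (rep in 1:5) {
    focal <- setNames(lapply(1:30, function(i) {
      sample(vocab, sample(1:3, 1))
    }), paste0("fp", 1:30))
    refs <- lapply(1:3, function(s) {
      setNames(lapply(1:10, function(i) sample(vocab, sample(1:3, 1))),
               paste0("s", s, "p", 1:10))
    })
    res <- screen_atypical_combinations(
      build_architectures(hits_for(focal)),
      lapply(refs, function(r) {
        combination_census(build_architectures(hits_for(r)))
      }),
      max_count = 4)
    expect_equal(sort(unique(tidy(res)$protein_id)),
                 bf_atypical(focal, refs, max_count = 4))
  }
})

test_that("reference species and max_count act monotonically", {
  set.seed(3)
  vocab <- LETTERS[1:5]
  focal <- setNames(lapply(1:25, function(i) sample(vocab, 2)),
                    paste0("p", 1:25))
  arch <- build_architectures(hits_for(focal))
  ref1 <- combination_census(build_architectures(
    hits_for(setNames(lapply(1:8, function(i) sample(vocab, 2)),
                      paste0("r1p", 1:8)))))
  ref2 <- combination_census(build_architectures(
    hits_for(setNames(lapply(1:8, function(i) sample(vocab, 2)),
                      paste0("r2p", 1:8)))))

  with1 <- unique(tidy(screen_atypical_combinations(arch, list(ref1)))$protein_id)
  with2 <- unique(tidy(screen_atypical_combinations(arch,
                                                    list(ref1, ref2)))$protein_id)
  expect_true(all(with2 %in% with1))

  loose <- unique(tidy(screen_atypical_combinations(arch, list(ref1),
                                                    max_count = 20))$protein_id)
  expect_true(all(with1 %in% loose))
})

test_that("family assignment supports multi-membership", {
  arch <- build_architectures(hits_for(list(
    pc = "Collagen", pb = c("Collagen", "Lectin_C"), px = "Other")))
  prot <- tibble::tibble(protein_id = c("pc", "pb", "px"),
                         gene_id = c("gc", "gb", "gx"),
                         length = c(300L, 400L, 500L))
  fam <- assign_families(arch, prot, c("Collagen", "Lectin_C"))
  expect_equal(nrow(fam), 3)
  expect_setequal(fam$family_accession[fam$protein_id == "pb"],
                  c("Collagen", "Lectin_C"))

  # membership counts equal a brute-force loop
  set.seed(44)
  fams100 <- setNames(lapply(1:100, function(i) {
    sample(c("Collagen", "Lectin_C", "Kinase"), sample(1:2, 1))
  }), sprintf("q%03d", 1:100))
  prot100 <- tibble::tibble(protein_id = names(fams100),
                            gene_id = names(fams100),
                            length = 100L + seq_len(100))
  fam100 <- assign_families(build_architectures(hits_for(fams100)),
                            prot100, c("Collagen", "Kinase"))
  manual <- sum(vapply(fams100, function(f) {
    sum(c("Collagen", "Kinase") %in% f)
  }, 1L))
  expect_equal(nrow(fam100), manual)
})

test_that("decile screen uses nearest-rank thresholds with strict flags", {
  fam <- tibble::tibble(family_accession = "F",
                        protein_id = paste0("p", 1:10),
                        length = seq(100L, 1000L, 100L))
  res <- screen_family_length_outliers(fam)
  expect_equal(glance(res)$d1, 100L)  # ceil(0.1*10) = rank 1
  expect_equal(glance(res)$d8, 800L)  # rank 8
  expect_setequal(tidy(res)$length, c(900L, 1000L))
  expect_true(all(tidy(res)$direction == "too-long"))

  equal_fam <- fam |> dplyr::mutate(length = 300L)
  expect_equal(nrow(tidy(screen_family_length_outliers(equal_fam))), 0)

  small <- fam[1:5, ]
  expect_message(res_small <- screen_family_length_outliers(small),
                 "skipping")
  expect_equal(nrow(res_small$families), 0)
})

test_that("decile screen flags at most 30% plus edge slack", {
  set.seed(21)
  for (n in c(10, 37, 100, 503)) {
    fam <- tibble::tibble(family_accession = "F",
                          protein_id = sprintf("p%04d", 1:n),
                          length = sample(10000:99999, n))  # distinct
    res <- screen_family_length_outliers(fam)
    expect_lte(nrow(tidy(res)) / n, 0.3 + 2 / n)
  }
})
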