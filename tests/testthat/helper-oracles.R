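# Independent brute-force oracles: deliberately naive loop implementations
# used to cross-check the vectorised screen code on small instances.

# pair-combination census by nested loops over proteins
bf_pair_census <- function(families_by_protein) {
  counts <- list()
  for (fams in families_by_protein) {
    fams <- sort(unique(fams))
    if (length(fams) < 2) next
    for (i in seq_len(length(fams) - 1)) {
      for (j in seq(i + 1, length(fams))) {
        key <- paste(fams[i], fams[j], sep = "+")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

# atypical-combination candidates by exhaustive check of every focal protein
bf_atypical <- function(focal_by_protein, ref_by_protein_list, max_count) {
  focal_census <- bf_pair_census(focal_by_protein)
  ref_keys <- character()
  for (ref in ref_by_protein_list) {
    ref_keys <- union(ref_keys, names(bf_pair_census(ref)))
  }
  out <- character()
  for (p in names(focal_by_protein)) {
    fams <- sort(unique(focal_by_protein[[p]]))
    if (length(fams) < 2) next
    for (i in seq_len(length(fams) - 1)) {
      for (j in seq(i + 1, length(fams))) {
        key <- paste(fams[i], fams[j], sep = "+")
        if (!key %in% ref_keys && focal_census[[key]] < max_count) {
          out <- union(out, p)
        }
      }
    }
  }
  sort(out)
}

# SSOG calling by scanning every protein's hits in a loop
bf_ssogs <- function(proteins, hits, set_roles, cutoff) {
  genes <- sort(unique(proteins$gene_id))
  res <- data.frame(gene_id = genes, is_ssog = TRUE,
                    has_orf_support = FALSE)
  for (k in seq_len(nrow(hits))) {
    if (hits$evalue[k] >= cutoff) next
    g <- proteins$gene_id[proteins$protein_id == hits$query_id[k]][1]
    role <- set_roles[[hits$subject_set[k]]]
    i <- which(res$gene_id == g)
    if (role == "homology") res$is_ssog[i] <- FALSE
    if (role == "orf_support") res$has_orf_support[i] <- TRUE
  }
  res
}

# Pearson r from the textbook sum formula
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
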