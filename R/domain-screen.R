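#' Build per-protein domain architectures
#'
#' Collapses significant domain hits into one architecture per protein: the
#' deduplicated set of domain families it contains. A protein with three
#' collagen-domain hits carries the collagen family once; proteins without
#' any significant hit are simply absent. Hits are expected to be
#' pre-filtered at the significance cutoff ([read_domtbl()] applies it).
#'
#' @param domain_hits tibble with `protein_id`, `domain_family`.
#' @return a tibble with one row per (protein, family):
#'   `protein_id`, `domain_family`.
#' @export
build_architectures <- function(domain_hits) {
  assert_cols(domain_hits, c("protein_id", "domain_family"), "domain hits")
  domain_hits |>
    distinct(.data$protein_id, .data$domain_family) |>
    arrange(.data$protein_id, .data$domain_family)
}

#' Enumerate domain combinations per protein
#'
#' In `"pairs"` mode (the default) a combination is an unordered pair of
#' distinct families within one protein -- an artificial fusion of two
#' single-domain genes introduces a novel pair, which is exactly the signal
#' the atypical-combination screen looks for. Single-family proteins yield no
#' pair. In `"full-set"` mode the whole architecture (sorted family set) is
#' one combination key.
#'
#' @param architectures output of [build_architectures()].
#' @param mode `"pairs"` or `"full-set"`.
#' @return a tibble with `protein_id`, `combination` (a canonical string key,
#'   families sorted and joined with `"+"`).
#' @export
domain_combinations <- function(architectures, mode = c("pairs", "full-set")) {
  mode <- match.arg(mode)
  assert_cols(architectures, c("protein_id", "domain_family"),
              "architecture table")
  fams <- architectures |>
    distinct(.data$protein_id, .data$domain_family) |>
    group_by(.data$protein_id) |>
    summarise(families = list(sort(.data$domain_family)), .groups = "drop")
  if (mode == "full-set") {
    out <- fams |>
      mutate(combination = purrr::map_chr(.data$families, paste,
                                          collapse = "+")) |>
      select("protein_id", "combination")
  } else {
    out <- fams |>
      mutate(pairs = purrr::map(.data$families, function(f) {
        if (length(f) < 2) return(character())
        cmb <- utils::combn(f, 2)
        paste(cmb[1, ], cmb[2, ], sep = "+")
      })) |>
      select("protein_id", "pairs") |>
      tidyr::unnest(cols = "pairs") |>
      rename(combination = "pairs")
  }
  structure(arrange(out, .data$protein_id, .data$combination),
            mode = mode, class = class(out))
}

#' Census of domain combinations across one proteome
#'
#' Counts, for every combination key, the number of proteins containing it --
#' proteins, not domain instances, so a protein contributes at most 1 to each
#' key.
#'
#' @inheritParams domain_combinations
#' @return a tibble with `combination`, `n_proteins`; carries a `"mode"`
#'   attribute so censuses built at different granularity cannot be mixed.
#' @export
combination_census <- function(architectures, mode = c("pairs", "full-set")) {
  mode <- match.arg(mode)
  combos <- domain_combinations(architectures, mode)
  out <- combos |>
    count(.data$combination, name = "n_proteins") |>
    arrange(.data$combination)
  attr(out, "mode") <- mode
  out
}

#' Screen for atypical domain combinations
#'
#' A focal protein is a candidate when it contains at least one domain
#' combination that (i) occurs in no reference species and (ii) is rare in
#' the focal species itself (fewer than `max_count` focal proteins carry
#' it). Such species-unique, low-frequency combinations are enriched for
#' artificial gene fusions, though genuine lineage-specific domain shuffling
#' also lands here.
#'
#' @param focal_architectures focal-species [build_architectures()] table.
#' @param reference_censuses list of [combination_census()] tibbles, one per
#'   reference species, built with the same `mode`.
#' @param max_count focal-frequency cutoff; combinations seen in
#'   `>= max_count` focal proteins are considered established. Default 10.
#' @param mode combination granularity, matching the reference censuses.
#' @return a `combination_screen` object; `tidy()` lists one row per
#'   (candidate protein, triggering combination).
#' @export
screen_atypical_combinations <- function(focal_architectures,
                                         reference_censuses,
                                         max_count = 10,
                                         mode = c("pairs", "full-set")) {
  mode <- match.arg(mode)
  stopifnot(is.list(reference_censuses), length(reference_censuses) >= 1)
  for (cen in reference_censuses) {
    cen_mode <- attr(cen, "mode")
    if (!is.null(cen_mode) && !identical(cen_mode, mode)) {
      abort(sprintf(
        "reference census built in '%s' mode, screen running in '%s' mode",
        cen_mode, mode))
    }
    assert_cols(cen, "combination", "reference census")
  }
  focal_combos <- domain_combinations(focal_architectures, mode)
  focal_census <- focal_combos |> count(.data$combination, name = "n_focal")
  ref_keys <- unique(unlist(lapply(reference_censuses,
                                   function(cen) cen$combination)))
  atypical <- focal_census |>
    filter(!.data$combination %in% ref_keys, .data$n_focal < max_count)
  candidates <- focal_combos |>
    semi_join(atypical, by = "combination") |>
    left_join(atypical, by = "combination") |>
    arrange(.data$protein_id, .data$combination)
  structure(
    list(candidates = candidates, max_count = max_count, mode = mode,
         n_focal_proteins = dplyr::n_distinct(focal_architectures$protein_id),
         n_reference_species = length(reference_censuses)),
    class = "combination_screen"
  )
}

#' @export
print.combination_screen <- function(x, ...) {
  cat(sprintf(
    "<combination_screen: %d candidate protein(s) with %d atypical %s combination(s)>\n",
    dplyr::n_distinct(x$candidates$protein_id),
    dplyr::n_distinct(x$candidates$combination), x$mode))
  invisible(x)
}

#' @rdname screen_atypical_combinations
#' @param x,object a `combination_screen`.
#' @param ... unused.
#' @method tidy combination_screen
#' @export
tidy.combination_screen <- function(x, ...) x$candidates

#' @rdname screen_atypical_combinations
#' @method glance combination_screen
#' @export
glance.combination_screen <- function(x, ...) {
  tibble(
    n_focal_proteins = x$n_focal_proteins,
    n_reference_species = x$n_reference_species,
    max_count = x$max_count, mode = x$mode,
    n_candidates = dplyr::n_distinct(x$candidates$protein_id),
    n_atypical_combinations = dplyr::n_distinct(x$candidates$combination)
  )
}

#' Assign proteins to Pfam-defined gene families
#'
#' A protein joins every listed family whose accession appears in its
#' architecture (multi-domain proteins can be members of several families);
#' its protein length is attached from the protein table.
#'
#' @param architectures [build_architectures()] table.
#' @param proteins protein table supplying lengths.
#' @param family_accessions character vector of screened family accessions.
#' @return a tibble with `family_accession`, `protein_id`, `length`.
#' @export
assign_families <- function(architectures, proteins, family_accessions) {
  stopifnot(length(family_accessions) >= 1)
  assert_cols(proteins, c("protein_id", "length"), "protein table")
  architectures |>
    filter(.data$domain_family %in% family_accessions) |>
    distinct(family_accession = .data$domain_family, .data$protein_id) |>
    left_join(proteins |> select("protein_id", "length"), by = "protein_id") |>
    arrange(.data$family_accession, .data$protein_id)
}

#' Screen gene families for protein length outliers
#'
#' Within each family the first and eighth length deciles are computed by the
#' nearest-rank rule ([nearest_rank()]); members strictly below the first
#' decile are flagged too-short and members strictly above the eighth decile
#' too-long, so roughly the lower 10% and upper 20% of each family are
#' selected while boundary members are kept. Families with fewer than
#' `min_members` members are skipped (deciles are meaningless there) with a
#' message.
#'
#' @param family_members output of [assign_families()].
#' @param min_members smallest family size screened. Default 10.
#' @return a `family_screen` object; `tidy()` lists candidates with their
#'   triggering family, direction and the family's decile thresholds;
#'   `glance()` summarises per-family counts.
#' @export
screen_family_length_outliers <- function(family_members, min_members = 10) {
  assert_cols(family_members, c("family_accession", "protein_id", "length"),
              "family membership table")
  sizes <- family_members |> count(.data$family_accession)
  skipped <- sizes$family_accession[sizes$n < min_members]
  if (length(skipped) > 0) {
    inform(sprintf("skipping %d famil%s with < %d members: %s",
                   length(skipped), if (length(skipped) == 1) "y" else "ies",
                   min_members, paste(skipped, collapse = ", ")))
  }
  screened <- family_members |>
    semi_join(sizes |> filter(.data$n >= min_members),
              by = "family_accession")
  if (nrow(screened) > 0) {
    screened <- screened |>
      group_by(.data$family_accession) |>
      mutate(d1 = nearest_rank(.data$length, 0.1),
             d8 = nearest_rank(.data$length, 0.8)) |>
      ungroup()
  } else {
    screened <- screened |> mutate(d1 = .data$length, d8 = .data$length)
  }
  candidates <- screened |>
    mutate(direction = dplyr::case_when(
      .data$length < .data$d1 ~ "too-short",
      .data$length > .data$d8 ~ "too-long",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$direction)) |>
    select("protein_id", "family_accession", "length", "direction",
           "d1", "d8") |>
    arrange(.data$protein_id, .data$family_accession)
  per_family <- screened |>
    group_by(.data$family_accession) |>
    summarise(n_members = n(), d1 = first(.data$d1), d8 = first(.data$d8),
              .groups = "drop")
  structure(
    list(candidates = candidates, families = per_family,
         members = screened, skipped = skipped, min_members = min_members),
    class = "family_screen"
  )
}

#' @export
print.family_screen <- function(x, ...) {
  cat(sprintf(
    "<family_screen: %d candidate(s) across %d screened famil%s (%d skipped)>\n",
    dplyr::n_distinct(x$candidates$protein_id), nrow(x$families),
    if (nrow(x$families) == 1) "y" else "ies", length(x$skipped)))
  invisible(x)
}

#' @rdname screen_family_length_outliers
#' @param x,object a `family_screen`.
#' @param ... unused.
#' @method tidy family_screen
#' @export
tidy.family_screen <- function(x, ...) x$candidates

#' @rdname screen_family_length_outliers
#' @method glance family_screen
#' @export
glance.family_screen <- function(x, ...) {
  x$families |>
    left_join(
      x$candidates |> count(.data$family_accession, name = "n_candidates"),
      by = "family_accession") |>
    mutate(n_candidates = dplyr::coalesce(.data$n_candidates, 0L))
}

#' @rdname screen_family_length_outliers
#' @method autoplot family_screen
#' @export
autoplot.family_screen <- function(object, ...) {
  df <- object$members |>
    left_join(object$candidates |>
                select("protein_id", "family_accession", "direction"),
              by = c("protein_id", "family_accession")) |>
    mutate(status = dplyr::coalesce(.data$direction, "within deciles"))
  ggplot2::ggplot(df, ggplot2::aes(.data$family_accession, .data$length)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey50") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$status),
                         width = 0.15, size = 0.8, alpha = 0.7) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "protein length (aa)", colour = NULL,
                  title = "Gene-family length distributions") +
    ggplot2::theme_minimal()
}
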