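#' Build ortholog pairs with longest-isoform protein lengths
#'
#' Joins a one-to-one ortholog table with the two proteomes. Each side
#' contributes the longest isoform of its gene ([longest_isoforms()]); the
#' pair carries both lengths and their exact ratio (focal / reference, no
#' pseudo-counts).
#'
#' @param pair_table tibble with `focal_gene`, `reference_gene`.
#' @param focal_proteins,reference_proteins protein tables
#'   (`protein_id`, `gene_id`, `length`).
#' @return a tibble of ortholog pairs: `focal_gene`, `reference_gene`,
#'   `focal_length`, `reference_length`, `ratio`.
#' @export
build_ortholog_pairs <- function(pair_table, focal_proteins,
                                 reference_proteins) {
  assert_cols(pair_table, c("focal_gene", "reference_gene"), "pair table")
  f <- longest_isoforms(focal_proteins) |>
    select("gene_id", focal_length = "length")
  r <- longest_isoforms(reference_proteins) |>
    select("gene_id", reference_length = "length")
  miss_f <- setdiff(pair_table$focal_gene, f$gene_id)
  miss_r <- setdiff(pair_table$reference_gene, r$gene_id)
  if (length(miss_f) + length(miss_r) > 0) {
    abort(paste0(
      "genes absent from their proteome: ",
      paste(c(miss_f, miss_r), collapse = ", ")))
  }
  pair_table |>
    left_join(f, by = c(focal_gene = "gene_id")) |>
    left_join(r, by = c(reference_gene = "gene_id")) |>
    mutate(ratio = .data$focal_length / .data$reference_length)
}

#' Pearson correlation of ortholog protein lengths
#'
#' @param pairs an ortholog pair tibble from [build_ortholog_pairs()].
#' @return Pearson's r of (focal length, reference length).
#' @export
length_correlation <- function(pairs) {
  assert_cols(pairs, c("focal_length", "reference_length"), "pair table")
  if (nrow(pairs) < 3) abort("need at least 3 ortholog pairs for a correlation")
  if (sd(pairs$focal_length) == 0 || sd(pairs$reference_length) == 0) {
    abort("degenerate length variance: correlation undefined")
  }
  cor(pairs$focal_length, pairs$reference_length, method = "pearson")
}

#' Screen ortholog pairs for protein length outliers
#'
#' Flags focal genes whose protein is unusually long or short relative to
#' their one-to-one reference ortholog: a pair is a candidate when its length
#' ratio reaches `cutoff` (too-long) or `1/cutoff` (too-short). The fold
#' boundary is inclusive by default (`ratio == cutoff` is flagged);
#' `strict = TRUE` demands a strictly greater/smaller ratio.
#'
#' @param pairs an ortholog pair tibble from [build_ortholog_pairs()].
#' @param cutoff fold-difference cutoff, > 1. Default 2 (two-fold).
#' @param strict flag only strict violations of the cutoff?
#' @return a `length_screen` object; [generics::tidy()] gives the candidate
#'   table (gene, direction, lengths, ratio), [generics::glance()] the
#'   summary (`n_pairs`, `pearson_r`, `cutoff`, `n_candidates`).
#' @export
#' @examples
#' pairs <- tibble::tibble(focal_gene = "PPA00494", reference_gene = "lev-8",
#'                         focal_length = 1094L, reference_length = 531L,
#'                         ratio = 1094 / 531)
#' generics::tidy(screen_length_outliers(pairs, compute_correlation = FALSE))
screen_length_outliers <- function(pairs, cutoff = 2, strict = FALSE,
                                   compute_correlation = TRUE) {
  assert_cols(pairs, c("focal_gene", "focal_length", "reference_length",
                       "ratio"), "pair table")
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 1) {
    abort("cutoff must be a single number > 1")
  }
  hi <- if (strict) pairs$ratio > cutoff else pairs$ratio >= cutoff
  lo <- if (strict) pairs$ratio < 1 / cutoff else pairs$ratio <= 1 / cutoff
  candidates <- pairs |>
    mutate(direction = dplyr::case_when(hi ~ "too-long", lo ~ "too-short",
                                        TRUE ~ NA_character_)) |>
    filter(!is.na(.data$direction)) |>
    select("focal_gene", "reference_gene", "direction", "focal_length",
           "reference_length", "ratio") |>
    arrange(.data$focal_gene)
  structure(
    list(
      candidates = candidates,
      pairs = tibble::as_tibble(pairs),
      cutoff = cutoff, strict = strict,
      pearson_r = if (compute_correlation) length_correlation(pairs) else NA_real_,
      n_pairs = nrow(pairs)
    ),
    class = "length_screen"
  )
}

#' @export
print.length_screen <- function(x, ...) {
  cat(sprintf(
    "<length_screen: %d / %d ortholog pairs beyond %s%.3g-fold (r = %.3f)>\n",
    nrow(x$candidates), x$n_pairs, if (x$strict) "> " else ">= ", x$cutoff,
    x$pearson_r))
  invisible(x)
}

#' @rdname screen_length_outliers
#' @param x a `length_screen` object.
#' @param ... unused.
#' @method tidy length_screen
#' @export
tidy.length_screen <- function(x, ...) x$candidates

#' @rdname screen_length_outliers
#' @method glance length_screen
#' @export
glance.length_screen <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, pearson_r = x$pearson_r, cutoff = x$cutoff,
         strict = x$strict, n_candidates = nrow(x$candidates))
}

#' @rdname screen_length_outliers
#' @param object a `length_screen` object (for `autoplot`).
#' @method autoplot length_screen
#' @export
autoplot.length_screen <- function(object, ...) {
  df <- object$pairs |>
    left_join(object$candidates |> select("focal_gene", "direction"),
              by = "focal_gene") |>
    mutate(status = dplyr::coalesce(.data$direction, "within cutoff"))
  ggplot2::ggplot(df, ggplot2::aes(.data$reference_length,
                                   .data$focal_length,
                                   colour = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "reference ortholog protein length (aa)",
      y = "focal protein length (aa)",
      colour = NULL,
      title = sprintf("Ortholog length comparison (n = %d, r = %.2f)",
                      object$n_pairs, object$pearson_r)) +
    ggplot2::theme_minimal()
}
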