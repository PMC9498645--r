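#' Over-representation analysis against a background universe
#'
#' For every annotation term, counts how many query genes it contains
#' (`observed`), computes the count expected if the query were drawn at
#' random from the universe (`expected = |query| * |term| / |universe|`), the
#' fold enrichment `observed / expected`, and an upper-tail hypergeometric
#' p-value `P(X >= observed)` (one-sided Fisher test) with population
#' `|universe|`, `|term|` successes and `|query|` draws. Terms observed fewer
#' than `min_observed` times are omitted.
#'
#' Query genes outside the universe are dropped with a message; annotation
#' members outside the universe are ignored.
#'
#' @param query Character vector of query gene symbols.
#' @param universe Character vector: the background gene universe (e.g. all
#'   genes represented on the expression array).
#' @param gene_sets Long annotation tibble (`set_id`, `name`, `namespace`,
#'   `gene`), see [read_gene_sets()].
#' @param min_observed Minimum observed count for a term to be reported.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted p-value column
#'   `p_adjusted` (the default report uses raw p-values).
#' @return A tibble with columns `term_id`, `term_name`, `namespace`,
#'   `observed`, `expected`, `fold`, `p_value` (and optionally `p_adjusted`).
#' @export
over_representation <- function(query, universe, gene_sets,
                                min_observed = 1, adjust = FALSE) {
  universe <- unique(normalize_gene_id(universe))
  if (length(universe) == 0) rlang::abort("background universe is empty")
  query <- unique(normalize_gene_id(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    rlang::inform(paste0(
      length(outside), " query gene(s) outside the universe dropped"
    ))
    query <- intersect(query, universe)
  }
  empty <- tibble::tibble(
    term_id = character(), term_name = character(), namespace = character(),
    observed = integer(), expected = double(), fold = double(),
    p_value = double()
  )
  if (length(query) == 0) {
    return(if (adjust) dplyr::mutate(empty, p_adjusted = double()) else empty)
  }
  ann <- dplyr::filter(gene_sets, .data$gene %in% universe)
  if (nrow(ann) == 0) {
    return(if (adjust) dplyr::mutate(empty, p_adjusted = double()) else empty)
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- ann |>
    dplyr::group_by(.data$set_id, .data$name, .data$namespace) |>
    dplyr::summarise(
      term_size = dplyr::n_distinct(.data$gene),
      observed = dplyr::n_distinct(intersect(.data$gene, query)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$observed >= min_observed) |>
    dplyr::mutate(
      expected = n_q * .data$term_size / n_u,
      fold = .data$observed / .data$expected,
      p_value = stats::phyper(
        .data$observed - 1, .data$term_size, n_u - .data$term_size, n_q,
        lower.tail = FALSE
      )
    ) |>
    dplyr::transmute(
      term_id = .data$set_id, term_name = .data$name,
      namespace = .data$namespace,
      observed = as.integer(.data$observed),
      expected = .data$expected, fold = .data$fold, p_value = .data$p_value
    )
  if (adjust) {
    rows <- dplyr::mutate(rows, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
  }
  rows
}

#' Rank enrichment rows by fold difference
#'
#' Sorts by fold enrichment descending, breaking ties by ascending p-value
#' and then lexicographically by term identifier, assigns ranks 1..n and
#' truncates to the top `top_n` rows.
#'
#' @param rows Tibble from [over_representation()].
#' @param top_n Number of rows to keep (default 20).
#' @return The ranked, truncated tibble with a `rank` column.
#' @export
rank_terms <- function(rows, top_n = 20) {
  stopifnot(top_n >= 1)
  rows |>
    dplyr::arrange(dplyr::desc(.data$fold), .data$p_value, .data$term_id) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(rank = dplyr::row_number())
}
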