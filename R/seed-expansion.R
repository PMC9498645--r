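SUBTYPES <- c("basal", "luminal", "her2")
AXES <- c("tf", "pathway", "coexpression")

#' Default seed marker configuration
#'
#' The packaged seed genes for the three molecular breast cancer subtypes:
#' 8 basal-like, 13 luminal-like and 2 Her2-positive markers, each an
#' established subtype-associated gene used as the starting point for
#' guilt-by-association expansion.
#'
#' @return A tibble with columns `gene`, `subtype`.
#' @export
#' @examples
#' dplyr::count(seed_markers(), subtype)
seed_markers <- function() {
  tibble::tibble(
    gene = c(
      "KRT5", "CDH3", "ID4", "FABP7", "KRT17", "TRIM29", "LAMC2", "ITGB4",
      "ESR1", "ESR2", "PGR", "CCND1", "FOXA1", "GATA3", "KRT18", "KRT8",
      "LAPTM4B", "SLC39A6", "SQLE", "TFF3", "XBP1",
      "ERBB2", "GRB7"
    ),
    subtype = c(rep("basal", 8), rep("luminal", 13), rep("her2", 2))
  )
}

#' Read a seed configuration table
#'
#' TSV with columns `gene` and `subtype`; subtype labels must be one of
#' `basal`, `luminal`, `her2`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `gene`, `subtype`.
#' @export
read_seed_markers <- function(path) {
  out <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("gene", "subtype") %in% names(out))) {
    rlang::abort("seed table must have columns 'gene' and 'subtype'")
  }
  out$gene <- normalize_gene_id(out$gene)
  out$subtype <- tolower(trimws(out$subtype))
  bad <- setdiff(unique(out$subtype), SUBTYPES)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown subtype label(s): ", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(out[, c("gene", "subtype")])
}

#' Expansion cut-off parameters
#'
#' Defaults are the pipeline's canonical settings: co-expression partners up
#' to mutual rank 2000 (the full ranked list a co-expression database
#' returns), interaction partners at combined score >= 0.150 (the low-
#' confidence threshold), at most 100 interaction partners per seed (the
#' first-shell cap).
#'
#' @param coexpr_max_rank Maximum mutual rank retained.
#' @param interaction_min_score Minimum interaction score retained.
#' @param interaction_max_partners Maximum interaction partners per seed.
#' @return A validated list of class `expansion_params`.
#' @export
expansion_params <- function(coexpr_max_rank = 2000,
                             interaction_min_score = 0.150,
                             interaction_max_partners = 100) {
  stopifnot(
    length(coexpr_max_rank) == 1, coexpr_max_rank >= 1,
    length(interaction_min_score) == 1, interaction_min_score > 0,
    interaction_min_score <= 1,
    length(interaction_max_partners) == 1, interaction_max_partners >= 1
  )
  structure(
    list(
      coexpr_max_rank = as.integer(coexpr_max_rank),
      interaction_min_score = interaction_min_score,
      interaction_max_partners = as.integer(interaction_max_partners)
    ),
    class = "expansion_params"
  )
}

new_axis_pool <- function(subtype, axis, evidence) {
  stopifnot(subtype %in% SUBTYPES, axis %in% AXES)
  evidence <- tibble::as_tibble(evidence)
  if (nrow(evidence) > 0) {
    evidence <- dplyr::distinct(evidence)
    # a candidate equal to its seed is only ever a self-target
    evidence$relation[evidence$candidate == evidence$seed] <- "self-target"
    evidence <- dplyr::distinct(evidence)
  }
  structure(
    list(
      subtype = subtype,
      axis = axis,
      genes = sort(unique(evidence$candidate)),
      evidence = evidence
    ),
    class = "axis_pool"
  )
}

empty_evidence <- function(axis) {
  tibble::tibble(
    candidate = character(), seed = character(), axis = character(),
    source_db = character(), relation = character()
  )
}

#' @export
print.axis_pool <- function(x, ...) {
  cat(
    "<axis_pool> ", x$subtype, "/", x$axis, ": ",
    length(x$genes), " genes, ", nrow(x$evidence), " evidence records from ",
    length(unique(x$evidence$source_db)), " source(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an axis pool into its evidence table
#'
#' @param x An `axis_pool`.
#' @param ... Unused.
#' @return The evidence tibble (`candidate`, `seed`, `axis`, `source_db`,
#'   `relation`) with `subtype` attached.
#' @export
tidy.axis_pool <- function(x, ...) {
  dplyr::mutate(x$evidence, subtype = x$subtype)
}

#' @rdname tidy.axis_pool
#' @export
glance.axis_pool <- function(x, ...) {
  tibble::tibble(
    subtype = x$subtype, axis = x$axis,
    n_genes = length(x$genes), n_evidence = nrow(x$evidence),
    n_sources = length(unique(x$evidence$source_db))
  )
}

#' Expand seeds through transcription-factor regulation
#'
#' For every seed gene the pool collects (a) each transcription factor with an
#' edge into the seed, (b) every known target of each such TF (co-regulated
#' genes), and (c) every target of the seed itself when the seed appears as a
#' TF. Activating, repressing and unsigned edges all count: inclusion is
#' binary and sign-blind.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param edges TF-edge tibble (see [read_tf_edges()]).
#' @param subtype Subtype label the pool belongs to.
#' @return An `axis_pool` for axis `"tf"`.
#' @export
expand_tf <- function(seeds, edges, subtype = "basal") {
  seeds <- unique(normalize_gene_id(seeds))
  if (nrow(edges) == 0 || length(seeds) == 0) {
    return(new_axis_pool(subtype, "tf", empty_evidence("tf")))
  }
  missing <- seeds[!(seeds %in% edges$target | seeds %in% edges$tf)]
  if (length(missing) > 0) {
    rlang::inform(paste0(
      "no regulatory data for seed(s): ", paste(missing, collapse = ", ")
    ))
  }
  per_seed <- purrr::map_dfr(seeds, function(s) {
    regs <- dplyr::filter(edges, .data$target == s)
    tf_records <- tibble::tibble(
      candidate = regs$tf, seed = s, axis = "tf",
      source_db = regs$source_db, relation = paste0("regulates-seed:", regs$tf)
    )
    shared <- dplyr::filter(edges, .data$tf %in% regs$tf)
    shared_records <- tibble::tibble(
      candidate = shared$target, seed = s, axis = "tf",
      source_db = shared$source_db, relation = paste0("shared-TF:", shared$tf)
    )
    own <- dplyr::filter(edges, .data$tf == s)
    own_records <- tibble::tibble(
      candidate = own$target, seed = s, axis = "tf",
      source_db = own$source_db, relation = "target-of-seed"
    )
    dplyr::bind_rows(tf_records, shared_records, own_records)
  })
  new_axis_pool(subtype, "tf", per_seed)
}

#' Expand seeds through pathway co-membership
#'
#' The pool is the union, over all seeds, of the members of every gene set
#' that contains the seed. Only `molecular_function`, `biological_process`
#' and `pathway` namespaces participate; `cellular_component` sets are
#' ignored. Seeds co-annotated with other seeds stay in the pool: nothing is
#' excluded.
#'
#' @param seeds Character vector of seed gene symbols.
#' @param gene_sets Long gene-set tibble (see [read_gene_sets()]).
#' @param subtype Subtype label the pool belongs to.
#' @return An `axis_pool` for axis `"pathway"`.
#' @export
expand_pathway <- function(seeds, gene_sets, subtype = "basal") {
  seeds <- unique(normalize_gene_id(seeds))
  usable <- dplyr::filter(
    gene_sets,
    .data$namespace %in% c("molecular_function", "biological_process", "pathway")
  )
  if (nrow(usable) == 0 || length(seeds) == 0) {
    return(new_axis_pool(subtype, "pathway", empty_evidence("pathway")))
  }
  hits <- usable |>
    dplyr::filter(.data$gene %in% seeds) |>
    dplyr::distinct(.data$set_id, seed = .data$gene)
  evidence <- hits |>
    dplyr::inner_join(usable, by = "set_id", relationship = "many-to-many") |>
    dplyr::transmute(
      candidate = .data$gene, seed = .data$seed, axis = "pathway",
      source_db = paste0("gmt:", .data$namespace),
      relation = paste0("set:", .data$set_id)
    )
  new_axis_pool(subtype, "pathway", evidence)
}

#' Expand seeds through co-expression and protein interaction
#'
#' The pool unions two evidence sources per seed: co-expression partners with
#' mutual rank at or below `coexpr_max_rank`, and interaction partners with
#' score at or above `interaction_min_score`, keeping at most
#' `interaction_max_partners` per seed in descending score order (ties broken
#' lexicographically by partner symbol, for determinism).
#'
#' @param seeds Character vector of seed gene symbols.
#' @param coexpr Co-expression tibble (see [read_coexpression()]).
#' @param interactions Interaction tibble (see [read_interactions()]).
#' @param params An [expansion_params()] object.
#' @param subtype Subtype label the pool belongs to.
#' @return An `axis_pool` for axis `"coexpression"`.
#' @export
expand_coexpression <- function(seeds, coexpr, interactions,
                                params = expansion_params(),
                                subtype = "basal") {
  stopifnot(inherits(params, "expansion_params"))
  seeds <- unique(normalize_gene_id(seeds))
  cx <- coexpr |>
    dplyr::filter(.data$query %in% seeds, .data$mutual_rank <= params$coexpr_max_rank) |>
    dplyr::transmute(
      candidate = .data$partner, seed = .data$query, axis = "coexpression",
      source_db = "coexpression_db",
      relation = paste0("mutual_rank:", format(.data$mutual_rank, trim = TRUE))
    )
  # unordered pairs: a seed can sit on either end
  inter_long <- dplyr::bind_rows(
    dplyr::transmute(interactions, seed = .data$a, partner = .data$b, score = .data$score),
    dplyr::transmute(interactions, seed = .data$b, partner = .data$a, score = .data$score)
  )
  pp <- inter_long |>
    dplyr::filter(
      .data$seed %in% seeds, .data$score >= params$interaction_min_score,
      .data$partner != .data$seed
    ) |>
    dplyr::group_by(.data$seed) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$partner, .by_group = TRUE) |>
    dplyr::slice_head(n = params$interaction_max_partners) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      candidate = .data$partner, seed = .data$seed, axis = "coexpression",
      source_db = "interaction_db",
      relation = paste0("interaction_score:", format(.data$score, trim = TRUE))
    )
  new_axis_pool(subtype, "coexpression", dplyr::bind_rows(cx, pp))
}

#' Union two evidence pools from the same axis
#'
#' Membership is binary: a gene found by one source, the other, or both is
#' included exactly once, but the evidence records of both sources are kept.
#'
#' @param pool_a,pool_b `axis_pool` objects sharing axis and subtype.
#' @return The combined `axis_pool`.
#' @export
combine_sources <- function(pool_a, pool_b) {
  stopifnot(inherits(pool_a, "axis_pool"), inherits(pool_b, "axis_pool"))
  if (pool_a$axis != pool_b$axis || pool_a$subtype != pool_b$subtype) {
    rlang::abort("combine_sources requires pools with identical axis and subtype")
  }
  new_axis_pool(
    pool_a$subtype, pool_a$axis,
    dplyr::bind_rows(pool_a$evidence, pool_b$evidence)
  )
}

#' Intersect the three evidence axes
#'
#' Only genes found on all three axes — transcriptional regulation, pathway
#' co-membership, and co-expression/interaction — are predictive markers.
#' Seeds that resurface through all three axes are valid predictions and are
#' not removed.
#'
#' @param tf,pathway,coexpression The three `axis_pool`s of one subtype.
#' @return Sorted character vector of predicted gene symbols.
#' @export
intersect_axes <- function(tf, pathway, coexpression) {
  pools <- list(tf, pathway, coexpression)
  stopifnot(all(purrr::map_lgl(pools, inherits, "axis_pool")))
  axes <- purrr::map_chr(pools, "axis")
  if (!identical(axes, AXES)) {
    rlang::abort("intersect_axes expects pools for axes tf, pathway, coexpression")
  }
  if (length(unique(purrr::map_chr(pools, "subtype"))) != 1) {
    rlang::abort("intersect_axes requires pools from one subtype")
  }
  sort(purrr::reduce(purrr::map(pools, "genes"), intersect))
}

#' Label predicted genes with the subtypes that produced them
#'
#' Each subtype run is independent; a gene surfacing in several runs is
#' labelled with each of them (a pan-subtype prediction sits in all three).
#'
#' @param results Named list mapping subtype label to a character vector of
#'   predicted genes.
#' @return A tibble with columns `gene`, `subtypes` (list of subtype labels)
#'   and `n_subtypes`.
#' @export
partition_subtypes <- function(results) {
  stopifnot(is.list(results), all(names(results) %in% SUBTYPES))
  long <- purrr::imap_dfr(results, function(genes, st) {
    tibble::tibble(gene = as.character(genes), subtype = st)
  })
  if (nrow(long) == 0) {
    return(tibble::tibble(
      gene = character(), subtypes = list(), n_subtypes = integer()
    ))
  }
  long |>
    dplyr::distinct() |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      subtypes = list(intersect(SUBTYPES, .data$subtype)),
      n_subtypes = length(.data$subtypes[[1]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene)
}

#' Partition predictions into the seven Venn regions
#'
#' @param partition Output of [partition_subtypes()].
#' @return Named list of the seven disjoint subtype-combination regions, each
#'   a sorted character vector of genes.
#' @export
venn_regions <- function(partition) {
  combos <- list(
    basal = "basal", luminal = "luminal", her2 = "her2",
    `basal&luminal` = c("basal", "luminal"),
    `basal&her2` = c("basal", "her2"),
    `luminal&her2` = c("luminal", "her2"),
    `basal&luminal&her2` = c("basal", "luminal", "her2")
  )
  purrr::map(combos, function(cmb) {
    hit <- purrr::map_lgl(partition$subtypes, ~ setequal(.x, cmb))
    sort(partition$gene[hit])
  })
}
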