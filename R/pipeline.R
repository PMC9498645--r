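#' Run configuration for a file-based pipeline run
#'
#' Collects the input paths and analysis settings of one end-to-end run.
#' Defaults are the pipeline's canonical settings: interaction score >= 0.150
#' with at most 100 partners per seed, co-expression mutual rank <= 2000, and
#' two-sided alpha 0.05 on 10 tumor/normal pairs.
#'
#' @param tf_edges Named character vector of TF-edge extract paths; names
#'   label the source databases.
#' @param gene_sets Character vector of GMT paths (one per source extract).
#' @param coexpression,interactions,topology,expression,samples,probe_map,seeds
#'   Paths to the corresponding single-file inputs.
#' @param id_map Optional path to an identifier-mapping table.
#' @param params An [expansion_params()] object.
#' @param alpha Two-sided significance level for the paired test.
#' @param enrichment_query Which validated gene list feeds the
#'   over-representation analysis: all significantly `"dysregulated"` genes
#'   (default) or only the `"upregulated"` ones.
#' @param out_dir Optional report directory; created by [run_pipeline()].
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(tf_edges, gene_sets, coexpression, interactions,
                       topology, expression, samples, probe_map, seeds,
                       id_map = NULL,
                       params = expansion_params(), alpha = 0.05,
                       enrichment_query = c("dysregulated", "upregulated"),
                       out_dir = NULL) {
  enrichment_query <- match.arg(enrichment_query)
  paths <- c(
    tf_edges, gene_sets, coexpression, interactions, topology,
    expression, samples, probe_map, seeds, id_map
  )
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (is.null(names(tf_edges))) {
    names(tf_edges) <- paste0("tf_db_", letters[seq_along(tf_edges)])
  }
  structure(
    list(
      tf_edges = tf_edges, gene_sets = gene_sets,
      coexpression = coexpression, interactions = interactions,
      topology = topology, expression = expression, samples = samples,
      probe_map = probe_map, seeds = seeds, id_map = id_map,
      params = params, alpha = alpha, enrichment_query = enrichment_query,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Mine candidate markers from in-memory knowledge bases
#'
#' The core guilt-by-association procedure, operating on tibbles. Each
#' subtype is processed independently: the three evidence axes are expanded
#' (unioning source extracts within each axis), intersected to the predicted
#' candidate set, and filtered to the secreted subset by membrane topology.
#' When an expression set is supplied, predictions are validated by paired
#' differential expression and tallied; when annotation sets are supplied,
#' over-representation of the validated genes is computed per namespace.
#'
#' @param seeds Seed tibble (`gene`, `subtype`), e.g. [seed_markers()].
#' @param tf_edges TF-edge tibble with a `source_db` column (sources are
#'   expanded separately, then unioned).
#' @param gene_sets A gene-set tibble or list of tibbles (one per source
#'   extract).
#' @param coexpression Co-expression tibble.
#' @param interactions Interaction tibble.
#' @param topology Topology annotation tibble.
#' @param es Optional [expression_set()] for validation.
#' @param probe_map Optional probe-to-gene tibble (required with `es`).
#' @param params An [expansion_params()] object.
#' @param alpha Two-sided significance level.
#' @param enrichment_query `"dysregulated"` (both directions, default) or
#'   `"upregulated"`.
#' @param universe Optional background universe for enrichment; defaults to
#'   all genes in `probe_map`.
#' @return An object of class `marker_run`; see [tidy.marker_run()].
#' @export
mine_markers <- function(seeds, tf_edges, gene_sets, coexpression,
                         interactions, topology,
                         es = NULL, probe_map = NULL,
                         params = expansion_params(), alpha = 0.05,
                         enrichment_query = c("dysregulated", "upregulated"),
                         universe = NULL) {
  enrichment_query <- match.arg(enrichment_query)
  if (!is.list(gene_sets) || is.data.frame(gene_sets)) {
    gene_sets <- list(gene_sets)
  }
  all_sets <- dplyr::bind_rows(gene_sets)
  subtypes_present <- intersect(SUBTYPES, unique(seeds$subtype))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  per_subtype <- purrr::map(subtypes_present, function(st) {
    sd_genes <- seeds$gene[seeds$subtype == st]
    # regulators are identified in any source and their target lists compiled
    # from all sources jointly, so TF edges are pooled before expansion
    tf_pool <- expand_tf(sd_genes, tf_edges, subtype = st)
    pw_pool <- gene_sets |>
      purrr::map(~ expand_pathway(sd_genes, .x, subtype = st)) |>
      purrr::reduce(combine_sources)
    cx_pool <- expand_coexpression(
      sd_genes, coexpression, interactions,
      params = params, subtype = st
    )
    candidates <- intersect_axes(tf_pool, pw_pool, cx_pool)
    secreted <- filter_secreted(candidates, topology)
    note(
      st, ": pools tf=", length(tf_pool$genes),
      " pathway=", length(pw_pool$genes),
      " coexpression=", length(cx_pool$genes),
      " -> intersection=", length(candidates),
      " -> secreted=", length(secreted)
    )
    list(
      subtype = st,
      pools = dplyr::bind_rows(
        glance(tf_pool), glance(pw_pool), glance(cx_pool)
      ),
      candidates = candidates,
      secreted = as.character(secreted),
      unannotated = attr(secreted, "unannotated")
    )
  })
  names(per_subtype) <- subtypes_present

  secreted_by_subtype <- purrr::map(per_subtype, "secreted")
  partition <- partition_subtypes(secreted_by_subtype)
  predicted_long <- purrr::imap_dfr(secreted_by_subtype, function(genes, st) {
    tibble::tibble(gene = genes, subtype = st)
  })

  validation <- NULL
  if (!is.null(es)) {
    if (is.null(probe_map)) rlang::abort("probe_map is required with an expression set")
    validation <- validate_markers(predicted_long, es, probe_map, alpha = alpha)
    sig <- sum(validation$results$direction != "ns")
    note(
      "validation: ", nrow(validation$results), " genes tested, ",
      sig, " significant at alpha=", alpha
    )
  }

  enrichment <- NULL
  if (!is.null(validation) && nrow(all_sets) > 0) {
    if (is.null(universe)) universe <- unique(probe_map$gene)
    res <- validation$results
    query <- switch(enrichment_query,
      dysregulated = res$gene[res$direction %in% c("up", "down")],
      upregulated = res$gene[res$direction == "up"]
    )
    enrichment <- purrr::map(
      rlang::set_names(c("biological_process", "cellular_component")),
      function(ns) {
        rows <- over_representation(
          query, universe,
          dplyr::filter(all_sets, .data$namespace == ns)
        )
        rank_terms(rows, top_n = 20)
      }
    )
    note(
      "enrichment (", enrichment_query, "): query of ", length(unique(query)),
      " genes against universe of ", length(unique(universe))
    )
  }

  counts <- purrr::map_dfr(per_subtype, function(ps) {
    n_sig <- if (is.null(validation)) {
      NA_integer_
    } else {
      sig_genes <- validation$results$gene[validation$results$direction != "ns"]
      length(intersect(ps$secreted, sig_genes))
    }
    tibble::tibble(
      subtype = ps$subtype,
      tf = ps$pools$n_genes[ps$pools$axis == "tf"],
      pathway = ps$pools$n_genes[ps$pools$axis == "pathway"],
      coexpression = ps$pools$n_genes[ps$pools$axis == "coexpression"],
      intersection = length(ps$candidates),
      secreted = length(ps$secreted),
      significant = n_sig
    )
  })

  structure(
    list(
      subtypes = per_subtype,
      partition = partition,
      venn = venn_regions(partition),
      validation = validation,
      enrichment = enrichment,
      counts = counts,
      params = params, alpha = alpha,
      enrichment_query = enrichment_query,
      log = log_lines
    ),
    class = "marker_run"
  )
}

#' Run the full pipeline from a file-based configuration
#'
#' Reads every input named in the configuration, executes [mine_markers()]
#' per subtype, and (when `out_dir` is set) writes the report files. Any
#' stage error aborts, naming the offending input.
#'
#' @param cfg A [run_config()].
#' @return A `marker_run` object, invisibly when a report is written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tf_edges <- purrr::imap_dfr(
    as.list(cfg$tf_edges),
    ~ read_tf_edges(.x, source_db = .y)
  )
  gene_sets <- purrr::map(cfg$gene_sets, read_gene_sets)
  run <- mine_markers(
    seeds = read_seed_markers(cfg$seeds),
    tf_edges = tf_edges,
    gene_sets = gene_sets,
    coexpression = read_coexpression(cfg$coexpression),
    interactions = read_interactions(cfg$interactions),
    topology = read_phobius_short(cfg$topology),
    es = read_expression_matrix(cfg$expression, cfg$samples),
    probe_map = read_probe_map(cfg$probe_map),
    params = cfg$params, alpha = cfg$alpha,
    enrichment_query = cfg$enrichment_query
  )
  if (!is.null(cfg$out_dir)) {
    write_report(run, cfg$out_dir)
    return(invisible(run))
  }
  run
}

#' @export
print.marker_run <- function(x, ...) {
  cat("<marker_run>\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a marker run into its per-gene marker table
#'
#' One row per predicted secreted marker gene, with the subtypes that
#' produced it and (when validation ran) the representative probe, effect
#' size, p-value and direction call.
#'
#' @param x A `marker_run`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `subtypes` (comma-separated),
#'   `n_subtypes` and, if validated, `probe`, `mean_log2_diff`, `p_value`,
#'   `ci_low`, `ci_high`, `direction`.
#' @export
tidy.marker_run <- function(x, ...) {
  out <- x$partition |>
    dplyr::mutate(subtypes = purrr::map_chr(.data$subtypes, paste, collapse = ","))
  if (!is.null(x$validation)) {
    out <- out |>
      dplyr::left_join(
        dplyr::select(
          x$validation$results, "gene", "probe", "mean_log2_diff",
          "p_value", "ci_low", "ci_high", "direction"
        ),
        by = "gene"
      ) |>
      dplyr::mutate(direction = dplyr::coalesce(.data$direction, "missing"))
  }
  out
}

#' @rdname tidy.marker_run
#' @export
glance.marker_run <- function(x, ...) {
  tly <- if (is.null(x$validation)) {
    NULL
  } else {
    dplyr::filter(x$validation$tally, .data$subtype == "total")
  }
  tibble::tibble(
    n_subtypes_run = nrow(x$counts),
    n_predicted = nrow(x$partition),
    n_pan_subtype = sum(x$partition$n_subtypes == 3),
    n_up = if (is.null(tly)) NA_integer_ else tly$up,
    n_down = if (is.null(tly)) NA_integer_ else tly$down,
    n_dysregulated = if (is.null(tly)) NA_integer_ else tly$up + tly$down,
    alpha = x$alpha
  )
}

#' Write the report files for a pipeline run
#'
#' Emits `markers.tsv` (the tidy marker table), `venn.json` (the seven
#' disjoint subtype regions), `tally.json`, `enrichment_bp.tsv` /
#' `enrichment_cc.tsv` (ranked over-representation tables), `summary.json`
#' (stage counts) and `run.log`. Reruns on identical inputs produce
#' identical tables (the log carries a timestamp line).
#'
#' @param run A `marker_run`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of files written.
#' @export
write_report <- function(run, out_dir) {
  stopifnot(inherits(run, "marker_run"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) rlang::abort(paste0("cannot create ", out_dir))
  p <- function(f) file.path(out_dir, f)
  files <- c(
    markers = p("markers.tsv"), venn = p("venn.json"),
    tally = p("tally.json"),
    enrichment_bp = p("enrichment_bp.tsv"),
    enrichment_cc = p("enrichment_cc.tsv"),
    summary = p("summary.json"), log = p("run.log")
  )
  readr::write_tsv(tidy(run), files["markers"])
  jsonlite::write_json(run$venn, files["venn"], pretty = TRUE)
  if (!is.null(run$validation)) {
    jsonlite::write_json(run$validation$tally, files["tally"],
      pretty = TRUE, digits = NA
    )
  } else {
    jsonlite::write_json(list(), files["tally"])
  }
  empty_enrich <- tibble::tibble(
    term_id = character(), term_name = character(), namespace = character(),
    observed = integer(), expected = double(), fold = double(),
    p_value = double(), rank = integer()
  )
  readr::write_tsv(
    if (is.null(run$enrichment)) empty_enrich else run$enrichment$biological_process,
    files["enrichment_bp"]
  )
  readr::write_tsv(
    if (is.null(run$enrichment)) empty_enrich else run$enrichment$cellular_component,
    files["enrichment_cc"]
  )
  jsonlite::write_json(
    list(
      counts = run$counts,
      alpha = run$alpha,
      enrichment_query = run$enrichment_query,
      params = unclass(run$params)
    ),
    files["summary"],
    pretty = TRUE, auto_unbox = TRUE, digits = NA
  )
  writeLines(
    c(paste0("# run written ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), run$log),
    files["log"]
  )
  invisible(files)
}

#' Plot validated markers as mean differences with confidence intervals
#'
#' A point-range chart of the per-gene mean paired log2 difference with its
#' t-based confidence interval, coloured by direction call — the standard way
#' to display paired tumor-vs-normal validation results.
#'
#' @param results Validation results tibble (from
#'   `marker_run$validation$results` or [validate_markers()]).
#' @return A ggplot object.
#' @export
plot_expression_ci <- function(results) {
  stopifnot(all(c("gene", "mean_log2_diff", "ci_low", "ci_high", "direction")
  %in% names(results)))
  results |>
    dplyr::mutate(gene = stats::reorder(.data$gene, .data$mean_log2_diff)) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$gene, y = .data$mean_log2_diff,
      ymin = .data$ci_low, ymax = .data$ci_high,
      colour = .data$direction
    )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(linewidth = 0.4, fatten = 1.5) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#5dade2", ns = "grey60")
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "mean paired log2(tumor) - log2(normal)",
      colour = "call"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_expression_ci
#' @param object A `marker_run` with validation results.
#' @param ... Unused.
#' @export
autoplot.marker_run <- function(object, ...) {
  if (is.null(object$validation)) {
    rlang::abort("marker_run has no validation results to plot")
  }
  plot_expression_ci(object$validation$results)
}

#' Plot ranked enrichment terms
#'
#' Bar chart of fold enrichment for the ranked terms of an
#' over-representation report.
#'
#' @param rows Ranked enrichment tibble (see [rank_terms()]).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows) {
  rows |>
    dplyr::mutate(
      label = paste(.data$term_id, .data$term_name),
      label = stats::reorder(.data$label, .data$fold)
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$label, y = .data$fold)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold enrichment (observed / expected)") +
    ggplot2::theme_minimal()
}
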