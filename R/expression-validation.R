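#' Construct a paired expression set
#'
#' Bundles a probes x samples matrix of log2 intensities with its sample
#' sheet. Every tumor sample must have exactly one paired normal sample from
#' the same subject (pair identifiers are bijective across the two
#' conditions), and all values must be finite.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param samples Tibble with columns `sample`, `condition` (`tumor` or
#'   `normal`) and `pair`.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, samples) {
  values <- as.matrix(values)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("sample", "condition", "pair") %in% names(samples)),
    !is.null(rownames(values)), !is.null(colnames(values))
  )
  samples$condition <- tolower(samples$condition)
  if (!all(samples$condition %in% c("tumor", "normal"))) {
    rlang::abort("condition must be 'tumor' or 'normal'")
  }
  if (!setequal(colnames(values), samples$sample)) {
    rlang::abort("sample sheet and matrix columns do not match")
  }
  if (!all(is.finite(values))) rlang::abort("expression values must be finite")
  tum <- samples$pair[samples$condition == "tumor"]
  nor <- samples$pair[samples$condition == "normal"]
  if (anyDuplicated(tum) || anyDuplicated(nor) || !setequal(tum, nor)) {
    rlang::abort("pair IDs must be bijective between tumor and normal samples")
  }
  samples <- samples[match(colnames(values), samples$sample), ]
  structure(list(values = values, samples = samples), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(
    "<expression_set> ", nrow(x$values), " probes x ", ncol(x$values),
    " samples (", sum(x$samples$condition == "tumor"), " tumor/normal pairs)\n",
    sep = ""
  )
  invisible(x)
}

#' Read a paired expression matrix from TSV files
#'
#' The matrix file has probe IDs in the first column (`probe`) and one column
#' per sample; the sample sheet has columns `sample`, `condition`, `pair`.
#' Values are taken to be on the log2 scale when `assume_log2 = TRUE`;
#' otherwise `log2(x + 1)` is applied on read.
#'
#' @param path Path to the expression TSV.
#' @param sample_path Path to the sample-sheet TSV.
#' @param assume_log2 Are the stored values already log2-scale?
#' @return An [expression_set()].
#' @export
read_expression_matrix <- function(path, sample_path, assume_log2 = TRUE) {
  mat_df <- readr::read_tsv(path, comment = "#", col_types = readr::cols())
  if (names(mat_df)[1] != "probe") {
    rlang::abort("expression matrix must have 'probe' as its first column")
  }
  values <- as.matrix(mat_df[, -1])
  rownames(values) <- mat_df$probe
  if (!assume_log2) values <- log2(values + 1)
  samples <- readr::read_tsv(
    sample_path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_character())
  )
  expression_set(values, samples)
}

#' Write an expression set to TSV files
#'
#' @param es An [expression_set()].
#' @param path Output path for the matrix TSV.
#' @param sample_path Output path for the sample sheet TSV.
#' @param comment Optional `#`-prefixed header lines for both files.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(es, path, sample_path, comment = NULL) {
  header <- paste(c("probe", colnames(es$values)), collapse = "\t")
  body <- paste(
    rownames(es$values),
    apply(es$values, 1, function(v) {
      paste(format(v, trim = TRUE, digits = 10, scientific = FALSE), collapse = "\t")
    }),
    sep = "\t"
  )
  writeLines(c(if (length(comment)) paste0("# ", comment), header, body), path)
  sheet <- c(
    if (length(comment)) paste0("# ", comment),
    "sample\tcondition\tpair",
    paste(es$samples$sample, es$samples$condition, es$samples$pair, sep = "\t")
  )
  writeLines(sheet, sample_path)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' TSV with columns `probe`, `gene`; several probes may map to one gene.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `probe`, `gene`.
#' @export
read_probe_map <- function(path) {
  out <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character())
  )
  if (!all(c("probe", "gene") %in% names(out))) {
    rlang::abort("probe map must have columns 'probe' and 'gene'")
  }
  if (anyDuplicated(out$probe)) rlang::abort("duplicated probe in probe map")
  out$gene <- normalize_gene_id(out$gene)
  tibble::as_tibble(out[, c("probe", "gene")])
}

# Within-pair tumor - normal differences for one or more probes (rows).
pair_differences <- function(es, probes) {
  s <- es$samples
  tum <- s[s$condition == "tumor", ]
  nor <- s[s$condition == "normal", ]
  nor <- nor[match(tum$pair, nor$pair), ]
  es$values[probes, tum$sample, drop = FALSE] -
    es$values[probes, nor$sample, drop = FALSE]
}

#' Two-sided paired t-test for one probe
#'
#' Tests the within-pair tumor minus normal log2 difference against zero.
#' The effect estimate is the mean paired difference (a log2 fold change),
#' with a t-based confidence interval at level `1 - alpha` on `n - 1` degrees
#' of freedom. The direction call is `up` when `p < alpha` and the mean
#' difference is positive, `down` when negative, otherwise `ns`.
#'
#' Degenerate inputs are reported rather than hidden: identical nonzero
#' differences across all pairs (zero variance) yield `p_value = 0` with
#' `degenerate = TRUE`; pairs that are all exactly equal yield `p_value = 1`
#' and `ns`.
#'
#' @param es An [expression_set()].
#' @param probe A probe ID present in the matrix.
#' @param alpha Two-sided significance level (default 0.05).
#' @return One-row tibble with columns `probe`, `mean_log2_diff`, `p_value`,
#'   `ci_low`, `ci_high`, `direction`, `n_pairs`, `degenerate`.
#' @export
paired_de_test <- function(es, probe, alpha = 0.05) {
  stopifnot(inherits(es, "expression_set"), alpha > 0, alpha < 1)
  if (!probe %in% rownames(es$values)) {
    rlang::abort(paste0("probe not in matrix: ", probe))
  }
  d <- as.numeric(pair_differences(es, probe))
  n <- length(d)
  if (n < 2) rlang::abort("paired test needs at least 2 complete pairs")
  m <- mean(d)
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    if (m == 0) {
      p <- 1
    } else {
      p <- 0
      degenerate <- TRUE
    }
    ci <- c(m, m)
  } else {
    tt <- stats::t.test(d, mu = 0, conf.level = 1 - alpha)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  direction <- if (p < alpha && m > 0) {
    "up"
  } else if (p < alpha && m < 0) {
    "down"
  } else {
    "ns"
  }
  tibble::tibble(
    probe = probe, mean_log2_diff = m, p_value = p,
    ci_low = ci[1], ci_high = ci[2],
    direction = direction, n_pairs = n, degenerate = degenerate
  )
}

#' t-based confidence interval for a sample mean
#'
#' Computes `mean(values) +/- t(1 - level/2, n - 1) * se`, where `level` is
#' the two-sided significance level (0.05 gives a 95% interval).
#'
#' @param values Numeric vector, length >= 2.
#' @param level Two-sided significance level in (0, 1).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' confidence_interval(c(0, 0, 0, 0, 2, 2, 2, 2), level = 0.05)
confidence_interval <- function(values, level = 0.05) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    rlang::abort("level must lie strictly between 0 and 1")
  }
  n <- length(values)
  if (n < 2) rlang::abort("confidence_interval needs at least 2 values")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  half <- stats::qt(1 - level / 2, df = n - 1) * se
  c(low = m - half, high = m + half)
}

#' Tally direction calls per subtype
#'
#' Summarizes a long table of (gene, subtype, direction) marker calls into
#' per-subtype counts of `up`, `down`, `ns` and `missing`, plus a grand-total
#' row in which each gene counts once even when predicted for several
#' subtypes (a gene's direction is the same wherever it appears, since it is
#' measured once).
#'
#' @param calls Tibble with columns `gene`, `subtype`, `direction`
#'   (`up`, `down`, `ns` or `missing`).
#' @return A tibble with columns `subtype`, `up`, `down`, `ns`, `missing`,
#'   `n`; the final row has `subtype = "total"` and is deduplicated by gene.
#' @export
tally_markers <- function(calls) {
  stopifnot(all(c("gene", "subtype", "direction") %in% names(calls)))
  dirs <- c("up", "down", "ns", "missing")
  bad <- setdiff(unique(calls$direction), dirs)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown direction label(s): ", paste(bad, collapse = ", ")))
  }
  count_block <- function(df, label) {
    counts <- table(factor(df$direction, levels = dirs))
    tibble::tibble(
      subtype = label,
      up = as.integer(counts["up"]), down = as.integer(counts["down"]),
      ns = as.integer(counts["ns"]), missing = as.integer(counts["missing"]),
      n = nrow(df)
    )
  }
  per_subtype <- calls |>
    dplyr::distinct(.data$gene, .data$subtype, .data$direction) |>
    dplyr::group_by(.data$subtype) |>
    dplyr::group_map(~ count_block(.x, .y$subtype)) |>
    dplyr::bind_rows()
  # keep canonical subtype order when applicable
  if (nrow(per_subtype) > 0) {
    per_subtype <- per_subtype[order(match(per_subtype$subtype, SUBTYPES)), ]
  }
  total <- calls |>
    dplyr::distinct(.data$gene, .data$direction) |>
    count_block("total")
  dplyr::bind_rows(per_subtype, total)
}

#' Validate predicted markers by paired differential expression
#'
#' Resolves each predicted gene to its probe(s), runs the paired t-test per
#' probe and, when several probes map to one gene, represents the gene by the
#' probe with the smallest p-value (a deterministic rule). Genes with no
#' probe on the array, or whose probes are absent from the matrix, are
#' counted as `missing`. Tallies are computed per subtype — a gene predicted
#' for several subtypes counts once in each — and once in the deduplicated
#' grand total.
#'
#' @param predicted Tibble with columns `gene`, `subtype` (one row per
#'   gene-subtype prediction).
#' @param es An [expression_set()].
#' @param probe_map Tibble with columns `probe`, `gene`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list with elements `results` (one row per gene: probe chosen,
#'   effect, p, CI, direction) and `tally` (see [tally_markers()]).
#' @export
validate_markers <- function(predicted, es, probe_map, alpha = 0.05) {
  stopifnot(all(c("gene", "subtype") %in% names(predicted)))
  predicted <- dplyr::mutate(predicted, gene = normalize_gene_id(.data$gene))
  genes <- sort(unique(predicted$gene))
  pm <- dplyr::filter(
    probe_map,
    .data$gene %in% genes, .data$probe %in% rownames(es$values)
  )
  results <- pm |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(function(df, key) {
      per_probe <- purrr::map_dfr(df$probe, ~ paired_de_test(es, .x, alpha))
      best <- dplyr::slice_min(per_probe, .data$p_value, n = 1, with_ties = FALSE)
      dplyr::mutate(best, gene = key$gene, .before = 1)
    }) |>
    dplyr::bind_rows()
  if (nrow(results) == 0) {
    results <- tibble::tibble(
      gene = character(), probe = character(), mean_log2_diff = double(),
      p_value = double(), ci_low = double(), ci_high = double(),
      direction = character(), n_pairs = integer(), degenerate = logical()
    )
  }
  missing_genes <- setdiff(genes, results$gene)
  if (length(missing_genes) > 0) {
    rlang::inform(paste0(
      length(missing_genes), " predicted gene(s) without expression data"
    ))
  }
  calls <- predicted |>
    dplyr::distinct(.data$gene, .data$subtype) |>
    dplyr::left_join(
      dplyr::select(results, "gene", "direction"),
      by = "gene"
    ) |>
    dplyr::mutate(direction = dplyr::coalesce(.data$direction, "missing"))
  list(
    results = dplyr::arrange(results, .data$p_value),
    tally = tally_markers(calls),
    missing = missing_genes
  )
}

#' Packaged table of validated secreted marker predictions
#'
#' A curated example dataset shipped with the package: extracellularly
#' targeted breast cancer marker genes with their HG-U133A probe IDs, the
#' molecular subtype(s) each was predicted for, and the direction of
#' significant differential expression in paired tumor/normal tissue
#' (21 upregulated, 37 downregulated genes).
#'
#' @return A tibble with columns `gene`, `uniprot`, `probe`, `basal`,
#'   `luminal`, `her2` (logical flags) and `direction`.
#' @export
#' @examples
#' validated_marker_table() |> dplyr::count(direction)
validated_marker_table <- function() {
  path <- system.file("extdata", "validated_markers.tsv", package = "markermine")
  out <- readr::read_tsv(path,
    comment = "#",
    col_types = readr::cols(
      gene = readr::col_character(), uniprot = readr::col_character(),
      probe = readr::col_character(), basal = readr::col_logical(),
      luminal = readr::col_logical(), her2 = readr::col_logical(),
      direction = readr::col_character()
    )
  )
  tibble::as_tibble(out)
}

#' Reshape the packaged marker table into long (gene, subtype, direction) form
#'
#' Convenience for feeding [validated_marker_table()] straight into
#' [tally_markers()].
#'
#' @param markers Wide marker table with logical subtype flag columns.
#' @return Long tibble with columns `gene`, `subtype`, `direction`.
#' @export
marker_table_long <- function(markers = validated_marker_table()) {
  markers |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(SUBTYPES),
      names_to = "subtype", values_to = "flag"
    ) |>
    dplyr::filter(.data$flag) |>
    dplyr::select("gene", "subtype", "direction")
}
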