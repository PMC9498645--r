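#' Normalize gene identifiers
#'
#' Trims whitespace and upper-cases symbols so that identifiers coming from
#' different knowledge-base extracts compare equal. Empty strings after
#' trimming are an error: readers must never emit empty identifiers.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of normalized identifiers.
#' @keywords internal
normalize_gene_id <- function(x) {
  out <- toupper(trimws(as.character(x)))
  if (any(!nzchar(out) | is.na(out))) {
    rlang::abort("empty or missing gene identifier after normalization")
  }
  out
}

# Read a tab-delimited extract, dropping "#"-prefixed comment lines but
# keeping track of original line numbers so parse errors can name them.
read_kb_lines <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  tibble::tibble(line = seq_along(lines)[keep], text = lines[keep])
}

#' Read transcription-factor edge tables
#'
#' Reads a tab-separated extract of TF -> target regulatory edges, the local
#' stand-in for a curated regulatory-interaction database. Three or four
#' columns are accepted: `tf`, `target` and an optional regulation `mode`
#' (`activation`, `repression` or `unknown`). A header line whose first token
#' is `tf` is skipped, as are `#`-prefixed comments. Edges with a blank or
#' unrecognized mode default to `unknown`: the sign of regulation does not
#' affect downstream candidate inclusion.
#'
#' @param path Path to a tab-delimited edge file.
#' @param source_db Label recorded with each edge, naming the originating
#'   extract (e.g. the database it was exported from).
#' @return A tibble with columns `tf`, `target`, `mode`, `source_db`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("tf\ttarget\tmode", "STAT3\tESR2\tactivation"), f)
#' read_tf_edges(f, source_db = "demo")
read_tf_edges <- function(path, source_db = "tf_extract") {
  rows <- read_kb_lines(path)
  if (nrow(rows) > 0) {
    first <- tolower(trimws(strsplit(rows$text[1], "\t", fixed = TRUE)[[1]]))
    # "TF" is also a gene symbol (transferrin): require the second header token
    if (first[1] == "tf" && length(first) >= 2 && first[2] == "target") {
      rows <- rows[-1, ]
    }
  }
  if (nrow(rows) == 0) {
    rlang::warn(paste0("no TF edges in ", path))
    return(tibble::tibble(
      tf = character(), target = character(),
      mode = character(), source_db = character()
    ))
  }
  fields <- strsplit(rows$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2 | nf > 4)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed TF edge row at line ", rows$line[bad[1]],
      " of ", path, ": expected 2-4 tab-separated fields, got ", nf[bad[1]]
    ))
  }
  modes <- purrr::map_chr(fields, function(f) {
    m <- if (length(f) >= 3) tolower(trimws(f[3])) else ""
    if (m %in% c("activation", "repression")) m else "unknown"
  })
  tibble::tibble(
    tf = normalize_gene_id(purrr::map_chr(fields, 1)),
    target = normalize_gene_id(purrr::map_chr(fields, 2)),
    mode = modes,
    source_db = source_db
  )
}

#' Write transcription-factor edges
#'
#' @param edges Tibble as returned by [read_tf_edges()].
#' @param path Output path.
#' @param comment Optional comment lines written as a `#`-prefixed header.
#' @return `path`, invisibly.
#' @export
write_tf_edges <- function(edges, path, comment = NULL) {
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    "tf\ttarget\tmode",
    paste(edges$tf, edges$target, edges$mode, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set identifier, description, then member gene symbols,
#' all tab-separated. The annotation namespace (`molecular_function`,
#' `biological_process`, `cellular_component` or `pathway`) is encoded in the
#' description field as a leading `ns=<value>` token; lines without one default
#' to `biological_process`. Members are de-duplicated and case-normalized.
#'
#' @param path Path to a GMT file.
#' @return A long tibble with one row per (set, member): columns `set_id`,
#'   `name`, `namespace`, `gene`.
#' @export
read_gene_sets <- function(path) {
  rows <- read_kb_lines(path)
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      set_id = character(), name = character(),
      namespace = character(), gene = character()
    ))
  }
  fields <- strsplit(rows$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed GMT line ", rows$line[bad[1]], " of ", path,
      ": expected >= 3 tab-separated fields, got ", nf[bad[1]]
    ))
  }
  ns_levels <- c(
    "molecular_function", "biological_process",
    "cellular_component", "pathway"
  )
  parsed <- purrr::map(fields, function(f) {
    desc <- trimws(f[2])
    ns <- "biological_process"
    m <- stringr::str_match(desc, "^ns=(\\S+)\\s*(.*)$")
    if (!is.na(m[1, 1])) {
      if (!m[1, 2] %in% ns_levels) {
        rlang::abort(paste0("unknown namespace token 'ns=", m[1, 2], "'"))
      }
      ns <- m[1, 2]
      desc <- m[1, 3]
    }
    members <- unique(normalize_gene_id(f[-(1:2)][nzchar(trimws(f[-(1:2)]))]))
    list(set_id = trimws(f[1]), name = desc, namespace = ns, members = members)
  })
  empty <- purrr::map_int(parsed, ~ length(.x$members)) < 1
  if (any(empty)) {
    rlang::warn(paste0(sum(empty), " gene set(s) with no members dropped"))
    parsed <- parsed[!empty]
  }
  ids <- purrr::map_chr(parsed, "set_id")
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicated set_id in ", path, ": ", ids[duplicated(ids)][1]))
  }
  purrr::map_dfr(parsed, function(p) {
    tibble::tibble(
      set_id = p$set_id, name = p$name,
      namespace = p$namespace, gene = p$members
    )
  })
}

#' Write gene sets in GMT format
#'
#' The namespace is encoded as a `ns=<value>` token prefixed to the
#' description, the convention [read_gene_sets()] understands.
#'
#' @param gene_sets Long tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @param comment Optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path, comment = NULL) {
  by_set <- gene_sets |>
    dplyr::group_by(.data$set_id, .data$name, .data$namespace) |>
    dplyr::summarise(members = paste(.data$gene, collapse = "\t"), .groups = "drop")
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    sprintf(
      "%s\tns=%s %s\t%s",
      by_set$set_id, by_set$namespace, by_set$name, by_set$members
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read ranked co-expression lists
#'
#' Tab-separated columns `query`, `partner`, `mutual_rank`. Mutual rank (MR)
#' is a symmetric co-expression statistic where 1 marks the strongest partner;
#' values must be numeric and >= 1, and partners of one query must not repeat.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `query`, `partner`, `mutual_rank`.
#' @export
read_coexpression <- function(path) {
  rows <- read_kb_lines(path)
  if (nrow(rows) > 0) {
    first <- tolower(trimws(strsplit(rows$text[1], "\t", fixed = TRUE)[[1]]))
    if (identical(first, c("query", "partner", "mutual_rank"))) rows <- rows[-1, ]
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      query = character(), partner = character(), mutual_rank = double()
    ))
  }
  fields <- strsplit(rows$text, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed co-expression row at line ", rows$line[bad[1]], " of ", path
    ))
  }
  mr <- suppressWarnings(as.numeric(purrr::map_chr(fields, 3)))
  if (anyNA(mr)) {
    rlang::abort(paste0(
      "non-numeric mutual rank at line ", rows$line[which(is.na(mr))[1]], " of ", path
    ))
  }
  if (any(mr < 1)) {
    rlang::abort("mutual_rank must be >= 1")
  }
  out <- tibble::tibble(
    query = normalize_gene_id(purrr::map_chr(fields, 1)),
    partner = normalize_gene_id(purrr::map_chr(fields, 2)),
    mutual_rank = mr
  )
  if (anyDuplicated(out[, c("query", "partner")])) {
    rlang::abort("duplicated (query, partner) pair in co-expression list")
  }
  out
}

#' @rdname read_coexpression
#' @param coexpr Tibble of co-expression edges.
#' @param comment Optional `#`-prefixed header lines.
#' @export
write_coexpression <- function(coexpr, path, comment = NULL) {
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    "query\tpartner\tmutual_rank",
    paste(coexpr$query, coexpr$partner, format(coexpr$mutual_rank, trim = TRUE, scientific = FALSE), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read scored protein-interaction edges
#'
#' Tab-separated columns `a`, `b`, `score` describing unordered protein pairs
#' with a combined confidence score on \[0, 1\]. Scores outside that range are
#' a validation error, not clipped.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `a`, `b`, `score`.
#' @export
read_interactions <- function(path) {
  rows <- read_kb_lines(path)
  if (nrow(rows) > 0) {
    first <- tolower(trimws(strsplit(rows$text[1], "\t", fixed = TRUE)[[1]]))
    if (identical(first, c("a", "b", "score"))) rows <- rows[-1, ]
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(a = character(), b = character(), score = double()))
  }
  fields <- strsplit(rows$text, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed interaction row at line ", rows$line[bad[1]], " of ", path
    ))
  }
  score <- suppressWarnings(as.numeric(purrr::map_chr(fields, 3)))
  if (anyNA(score)) {
    rlang::abort(paste0(
      "non-numeric interaction score at line ",
      rows$line[which(is.na(score))[1]], " of ", path
    ))
  }
  if (any(score < 0 | score > 1)) {
    rlang::abort("interaction score outside [0, 1]")
  }
  tibble::tibble(
    a = normalize_gene_id(purrr::map_chr(fields, 1)),
    b = normalize_gene_id(purrr::map_chr(fields, 2)),
    score = score
  )
}

#' @rdname read_interactions
#' @param interactions Tibble of interaction edges.
#' @param comment Optional `#`-prefixed header lines.
#' @export
write_interactions <- function(interactions, path, comment = NULL) {
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    "a\tb\tscore",
    paste(interactions$a, interactions$b,
      format(interactions$score, trim = TRUE, scientific = FALSE),
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an identifier-mapping table
#'
#' Two tab-separated columns, `raw_id` and `symbol`, mapping source-database
#' identifiers (UniProt accessions, probe IDs, aliases) many-to-one onto
#' harmonized gene symbols.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `raw_id`, `symbol`.
#' @export
read_id_map <- function(path) {
  rows <- read_kb_lines(path)
  if (nrow(rows) > 0) {
    first <- strsplit(rows$text[1], "\t", fixed = TRUE)[[1]]
    if (tolower(trimws(first[1])) == "raw_id") rows <- rows[-1, ]
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(raw_id = character(), symbol = character()))
  }
  fields <- strsplit(rows$text, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed ID-map row at line ", rows$line[bad[1]], " of ", path))
  }
  out <- tibble::tibble(
    raw_id = toupper(trimws(purrr::map_chr(fields, 1))),
    symbol = normalize_gene_id(purrr::map_chr(fields, 2))
  )
  if (any(!nzchar(out$raw_id))) rlang::abort("empty raw_id in ID map")
  dup <- out |>
    dplyr::distinct() |>
    dplyr::count(.data$raw_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::warn(paste0(
      "ambiguous (many-to-many) raw_id(s) in ID map, first kept: ",
      paste(utils::head(dup$raw_id, 5), collapse = ", ")
    ))
  }
  dplyr::distinct(out, .data$raw_id, .keep_all = TRUE)
}

#' @rdname read_id_map
#' @param id_map Tibble with columns `raw_id`, `symbol`.
#' @param comment Optional `#`-prefixed header lines.
#' @export
write_id_map <- function(id_map, path, comment = NULL) {
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    "raw_id\tsymbol",
    paste(id_map$raw_id, id_map$symbol, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Harmonize raw identifiers to gene symbols
#'
#' Resolves raw identifiers through an ID map so that candidate sets from
#' different knowledge bases can be combined on one namespace. Identifiers
#' that are already harmonized symbols (i.e. appear as mapping targets) pass
#' through unchanged, which makes the operation idempotent. Unmapped
#' identifiers are excluded from the result and reported via a message and the
#' `"unmapped"` attribute rather than raising: no source database is assumed
#' complete.
#'
#' @param ids Character vector of raw identifiers.
#' @param id_map Tibble with columns `raw_id`, `symbol` (see [read_id_map()]).
#' @return Character vector of unique harmonized symbols, with attribute
#'   `unmapped` listing identifiers that could not be resolved.
#' @export
#' @examples
#' harmonize(c("P15692"), tibble::tibble(raw_id = "P15692", symbol = "VEGFA"))
harmonize <- function(ids, id_map) {
  if (length(ids) == 0) {
    return(structure(character(), unmapped = character()))
  }
  ids_norm <- toupper(trimws(ids))
  hit <- match(ids_norm, id_map$raw_id)
  mapped <- id_map$symbol[hit]
  # already-harmonized symbols resolve to themselves
  self <- is.na(hit) & ids_norm %in% id_map$symbol
  mapped[self] <- ids_norm[self]
  unmapped <- unique(ids_norm[is.na(mapped)])
  if (length(unmapped) > 0) {
    rlang::inform(paste0(
      length(unmapped), " of ", length(unique(ids_norm)),
      " identifier(s) unmapped and excluded"
    ))
  }
  structure(unique(mapped[!is.na(mapped)]), unmapped = unmapped)
}
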