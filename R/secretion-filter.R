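TOPOLOGY_CLASSES <- c("secreted", "sp_and_tm", "tm_only", "neither")

#' Read Phobius short-format topology predictions
#'
#' Parses the four whitespace-delimited columns of Phobius "short" output:
#' sequence identifier, number of predicted transmembrane segments (TM),
#' signal-peptide call (`Y` for present, `0` or `N` for absent) and the raw
#' topology prediction string. A header line starting with `SEQENCE` (the
#' tool's spelling) or `SEQUENCE` is skipped, as are `#` comments.
#'
#' @param path Path to a Phobius short output file.
#' @return A tibble with columns `protein`, `tm_count`, `signal_peptide`,
#'   `prediction`.
#' @export
read_phobius_short <- function(path) {
  rows <- read_kb_lines(path)
  if (nrow(rows) > 0) {
    first_tok <- toupper(sub("\\s.*$", "", trimws(rows$text[1])))
    if (first_tok %in% c("SEQENCE", "SEQUENCE")) rows <- rows[-1, ]
  }
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      protein = character(), tm_count = integer(),
      signal_peptide = logical(), prediction = character()
    ))
  }
  fields <- strsplit(trimws(rows$text), "\\s+")
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "malformed topology row at line ", rows$line[bad[1]], " of ", path
    ))
  }
  tm_raw <- purrr::map_chr(fields, 2)
  tm <- suppressWarnings(as.integer(tm_raw))
  if (anyNA(tm) || any(tm < 0)) {
    i <- which(is.na(tm) | tm < 0)[1]
    rlang::abort(paste0(
      "non-integer or negative TM count '", tm_raw[i],
      "' at line ", rows$line[i], " of ", path
    ))
  }
  sp_raw <- toupper(purrr::map_chr(fields, 3))
  known <- sp_raw %in% c("Y", "0", "N")
  if (!all(known)) {
    i <- which(!known)[1]
    rlang::abort(paste0(
      "unknown signal-peptide token '", sp_raw[i],
      "' at line ", rows$line[i], " of ", path
    ))
  }
  tibble::tibble(
    protein = normalize_gene_id(purrr::map_chr(fields, 1)),
    tm_count = tm,
    signal_peptide = sp_raw == "Y",
    prediction = purrr::map_chr(fields, function(f) {
      if (length(f) >= 4) paste(f[-(1:3)], collapse = " ") else NA_character_
    })
  )
}

#' Write Phobius short-format topology predictions
#'
#' @param annotations Tibble as returned by [read_phobius_short()].
#' @param path Output path.
#' @param comment Optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_phobius_short <- function(annotations, path, comment = NULL) {
  pred <- annotations$prediction
  pred[is.na(pred)] <- "-"
  lines <- c(
    if (length(comment)) paste0("# ", comment),
    "SEQENCE ID                     TM SP PREDICTION",
    sprintf(
      "%-30s %2d %s  %s",
      annotations$protein, annotations$tm_count,
      ifelse(annotations$signal_peptide, "Y", "0"), pred
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Classify proteins by membrane topology
#'
#' Four exhaustive, mutually exclusive classes drive the secretome filter: a
#' protein with a signal peptide and no transmembrane segment is `secreted`
#' (extracellular space is its most likely destination); signal peptide plus
#' one or more TM segments is `sp_and_tm`; TM segments without a signal
#' peptide is `tm_only`; neither feature is `neither`.
#'
#' @param annotations Tibble with columns `protein`, `tm_count`,
#'   `signal_peptide` (see [read_phobius_short()]).
#' @return The input tibble with a `class` factor column added.
#' @export
#' @examples
#' classify_topology(tibble::tibble(
#'   protein = "TFF3", tm_count = 0L, signal_peptide = TRUE
#' ))
classify_topology <- function(annotations) {
  stopifnot(all(c("protein", "tm_count", "signal_peptide") %in% names(annotations)))
  if (any(annotations$tm_count < 0)) rlang::abort("tm_count must be >= 0")
  cls <- dplyr::case_when(
    annotations$signal_peptide & annotations$tm_count == 0 ~ "secreted",
    annotations$signal_peptide & annotations$tm_count > 0 ~ "sp_and_tm",
    !annotations$signal_peptide & annotations$tm_count > 0 ~ "tm_only",
    TRUE ~ "neither"
  )
  dplyr::mutate(annotations, class = factor(cls, levels = TOPOLOGY_CLASSES))
}

#' Count proteins per topology class
#'
#' The four classes partition the annotated proteins, so the counts always
#' sum to the number of annotations.
#'
#' @param annotations Topology annotation tibble.
#' @return A tibble with columns `class`, `n`, one row per class (zeros kept).
#' @export
topology_counts <- function(annotations) {
  classify_topology(annotations) |>
    dplyr::count(.data$class, .drop = FALSE) |>
    tibble::as_tibble()
}

#' Select the secreted subset of a candidate set
#'
#' Keeps candidates whose topology class is `secreted`. Candidates with no
#' annotation cannot be classified; they are excluded and reported through a
#' message and the `"unannotated"` attribute, mirroring the tolerance of
#' incomplete sources elsewhere in the pipeline.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param annotations Topology annotation tibble.
#' @return Sorted character vector of secreted candidates, with attribute
#'   `unannotated`.
#' @export
filter_secreted <- function(candidates, annotations) {
  candidates <- unique(normalize_gene_id(candidates))
  if (length(candidates) == 0) {
    return(structure(character(), unannotated = character()))
  }
  classed <- classify_topology(annotations)
  unannotated <- sort(setdiff(candidates, classed$protein))
  if (length(unannotated) > 0) {
    rlang::inform(paste0(
      length(unannotated), " candidate(s) without topology annotation excluded"
    ))
  }
  secreted <- classed$protein[classed$class == "secreted"]
  structure(
    sort(intersect(candidates, secreted)),
    unannotated = unannotated
  )
}
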