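#' Configuration for the synthetic study generator
#'
#' Describes a synthetic study whose structure mirrors the real inputs of the
#' mining pipeline: three subtype seed panels (8 basal / 13 luminal / 2 Her2
#' seeds), knowledge-base extracts with two source files per evidence axis,
#' topology predictions, and a paired tumor/normal expression matrix with 10
#' pairs, log2-scale intensities, planted effect sizes of +/- 2 log2 units and
#' Gaussian noise of sd 0.5.
#'
#' Planted markers are connected to a seed of their subtype on all three
#' axes; decoy genes are disconnected from each axis independently with
#' probability `decoy_axis_dropout` (at 1.0 a decoy never touches a seed, so
#' pipeline recovery of the planted set is exact by construction).
#'
#' @param n_genes Total gene universe size (seeds + planted + decoys).
#' @param n_tfs Number of transcription factors mediating planted links.
#' @param seeds_per_subtype Named integer vector of seed counts.
#' @param n_planted_markers Number of planted marker genes.
#' @param planted_secreted_fraction Fraction of planted markers given
#'   secreted topology (signal peptide, no TM segment).
#' @param effect_log2fc Planted tumor-vs-normal shift in log2 units.
#' @param noise_sd Per-measurement Gaussian noise sd.
#' @param n_pairs Number of tumor/normal sample pairs.
#' @param pair_sd Sd of the shared pair-level offset inducing within-pair
#'   correlation.
#' @param decoy_axis_dropout Per-axis probability that a decoy is left
#'   disconnected from that axis.
#' @param rng_seed Integer seed governing all randomness.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 150,
                         n_tfs = 12,
                         seeds_per_subtype = c(basal = 8, luminal = 13, her2 = 2),
                         n_planted_markers = 12,
                         planted_secreted_fraction = 1.0,
                         effect_log2fc = 2.0,
                         noise_sd = 0.5,
                         n_pairs = 10,
                         pair_sd = 0.3,
                         decoy_axis_dropout = 1.0,
                         rng_seed = 1L) {
  stopifnot(
    all(sort(names(seeds_per_subtype)) == sort(SUBTYPES)),
    all(seeds_per_subtype >= 1),
    n_planted_markers >= 1, n_tfs >= 1,
    planted_secreted_fraction >= 0, planted_secreted_fraction <= 1,
    decoy_axis_dropout >= 0, decoy_axis_dropout <= 1,
    noise_sd > 0, pair_sd >= 0, n_pairs >= 2,
    rng_seed == as.integer(rng_seed), rng_seed < 2^31 - 10
  )
  if (n_planted_markers + sum(seeds_per_subtype) > n_genes) {
    rlang::abort("infeasible config: planted markers + seeds exceed n_genes")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
      seeds_per_subtype = seeds_per_subtype,
      n_planted_markers = as.integer(n_planted_markers),
      planted_secreted_fraction = planted_secreted_fraction,
      effect_log2fc = effect_log2fc, noise_sd = noise_sd,
      n_pairs = as.integer(n_pairs), pair_sd = pair_sd,
      decoy_axis_dropout = decoy_axis_dropout,
      rng_seed = as.integer(rng_seed)
    ),
    class = "synth_config"
  )
}

synth_truth <- function(cfg) {
  seeds <- purrr::imap_dfr(
    as.list(cfg$seeds_per_subtype)[SUBTYPES],
    function(n, st) {
      tibble::tibble(
        gene = sprintf("%sSEED%02d", toupper(substr(st, 1, 3)), seq_len(n)),
        subtype = st
      )
    }
  )
  n_decoys <- cfg$n_genes - nrow(seeds) - cfg$n_planted_markers
  planted <- tibble::tibble(
    gene = sprintf("MARK%03d", seq_len(cfg$n_planted_markers)),
    subtype = SUBTYPES[(seq_len(cfg$n_planted_markers) - 1) %% 3 + 1],
    direction = c("up", "down")[(seq_len(cfg$n_planted_markers) - 1) %% 2 + 1],
    secreted = seq_len(cfg$n_planted_markers) <=
      round(cfg$planted_secreted_fraction * cfg$n_planted_markers)
  )
  list(
    seeds = seeds,
    planted = planted,
    decoys = sprintf("DECOY%03d", seq_len(n_decoys)),
    tfs = sprintf("TF%02d", seq_len(cfg$n_tfs))
  )
}

#' Generate a synthetic knowledge base with planted ground truth
#'
#' Emits TF edges (two source extracts), gene sets (two source extracts,
#' including decoy-only cellular-component sets that the pathway axis must
#' ignore), ranked co-expression lists, scored interactions, and an ID map.
#' Every planted marker is linked to at least one seed of its subtype on all
#' three axes; each planted link lives entirely in one randomly chosen source
#' extract of its axis, so recovering the full planted set requires union
#' within axes. Decoys are connected to a seed on each axis independently
#' with probability `1 - decoy_axis_dropout`; background noise edges touch
#' only decoys and can never create a seed link. Deterministic given
#' `cfg$rng_seed`.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `tf_edges`, `gene_sets_a`, `gene_sets_b`,
#'   `coexpression`, `interactions`, `id_map`, `truth`.
#' @export
generate_knowledge_base <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  truth <- synth_truth(cfg)
  withr::with_seed(cfg$rng_seed, {
    planted <- truth$planted
    seeds <- truth$seeds
    modes <- c("activation", "repression", "unknown")

    seed_for <- function(st, i) {
      pool <- seeds$gene[seeds$subtype == st]
      pool[(i - 1) %% length(pool) + 1]
    }

    # --- TF axis: one TF chain (TF -> seed, TF -> marker) per planted gene
    tf_rows <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      s <- seed_for(planted$subtype[i], i)
      t <- truth$tfs[(i - 1) %% cfg$n_tfs + 1]
      src <- sample(c("tf_db_a", "tf_db_b"), 1)
      tibble::tibble(
        tf = t, target = c(s, planted$gene[i]),
        mode = sample(modes, 2, replace = TRUE), source_db = src
      )
    })
    # decoy links (per-axis connection with prob 1 - dropout)
    connect <- function() stats::runif(length(truth$decoys)) > cfg$decoy_axis_dropout
    dc <- connect()
    if (any(dc)) {
      tf_rows <- dplyr::bind_rows(tf_rows, purrr::map_dfr(which(dc), function(j) {
        st <- sample(SUBTYPES, 1)
        s <- sample(seeds$gene[seeds$subtype == st], 1)
        t <- sample(truth$tfs, 1)
        tibble::tibble(
          tf = t, target = c(s, truth$decoys[j]),
          mode = sample(modes, 2, replace = TRUE),
          source_db = sample(c("tf_db_a", "tf_db_b"), 1)
        )
      }))
    }
    # decoy-only background regulators
    n_bg <- min(30, length(truth$decoys))
    if (n_bg >= 2) {
      bg_t <- sprintf("DTF%02d", 1:3)
      tf_rows <- dplyr::bind_rows(tf_rows, tibble::tibble(
        tf = sample(bg_t, n_bg, replace = TRUE),
        target = sample(truth$decoys, n_bg),
        mode = sample(modes, n_bg, replace = TRUE),
        source_db = sample(c("tf_db_a", "tf_db_b"), n_bg, replace = TRUE)
      ))
    }
    tf_rows <- dplyr::distinct(tf_rows)

    # --- pathway axis: one gene set per planted link, split across extracts
    ns_opts <- c("molecular_function", "biological_process", "pathway")
    set_rows <- purrr::map_dfr(seq_len(nrow(planted)), function(i) {
      s <- seed_for(planted$subtype[i], i)
      tibble::tibble(
        set_id = sprintf("SET:%04d", i),
        name = sprintf("planted pathway %d", i),
        namespace = sample(ns_opts, 1),
        gene = c(s, planted$gene[i]),
        extract = sample(c("a", "b"), 1)
      )
    })
    dc <- connect()
    if (any(dc)) {
      set_rows <- dplyr::bind_rows(set_rows, purrr::map_dfr(which(dc), function(j) {
        st <- sample(SUBTYPES, 1)
        s <- sample(seeds$gene[seeds$subtype == st], 1)
        tibble::tibble(
          set_id = sprintf("SET:D%03d", j),
          name = sprintf("decoy link pathway %d", j),
          namespace = sample(ns_opts, 1),
          gene = c(s, truth$decoys[j]),
          extract = sample(c("a", "b"), 1)
        )
      }))
    }
    # cellular-component sets mixing seeds and decoys: must be ignored
    cc_members <- unique(c(
      sample(seeds$gene, min(5, nrow(seeds))),
      sample(truth$decoys, min(10, length(truth$decoys)))
    ))
    set_rows <- dplyr::bind_rows(
      set_rows,
      tibble::tibble(
        set_id = "SET:CC01", name = "synthetic compartment",
        namespace = "cellular_component", gene = cc_members,
        extract = sample(c("a", "b"), 1)
      ),
      tibble::tibble(
        set_id = "SET:BG01", name = "decoy-only process",
        namespace = "biological_process",
        gene = sample(truth$decoys, min(8, length(truth$decoys))),
        extract = sample(c("a", "b"), 1)
      )
    )

    # --- co-expression / interaction axis
    via_coexpr <- stats::runif(nrow(planted)) < 0.5
    cx_rows <- purrr::map_dfr(which(via_coexpr), function(i) {
      tibble::tibble(
        query = seed_for(planted$subtype[i], i),
        partner = planted$gene[i],
        mutual_rank = sample(seq_len(expansion_params()$coexpr_max_rank), 1)
      )
    })
    pp_rows <- purrr::map_dfr(which(!via_coexpr), function(i) {
      tibble::tibble(
        a = seed_for(planted$subtype[i], i),
        b = planted$gene[i],
        score = round(stats::runif(1, 0.150, 1), 3)
      )
    })
    dc <- connect()
    if (any(dc)) {
      for (j in which(dc)) {
        st <- sample(SUBTYPES, 1)
        s <- sample(seeds$gene[seeds$subtype == st], 1)
        if (stats::runif(1) < 0.5) {
          cx_rows <- dplyr::bind_rows(cx_rows, tibble::tibble(
            query = s, partner = truth$decoys[j],
            mutual_rank = sample(seq_len(expansion_params()$coexpr_max_rank), 1)
          ))
        } else {
          pp_rows <- dplyr::bind_rows(pp_rows, tibble::tibble(
            a = s, b = truth$decoys[j], score = round(stats::runif(1, 0.150, 1), 3)
          ))
        }
      }
    }
    # sub-threshold background: beyond-rank co-expression and low-score
    # interactions between seeds and decoys (present in the files, excluded
    # by the cut-offs), plus decoy-decoy co-expression
    n_bg <- min(20, length(truth$decoys))
    cx_rows <- dplyr::bind_rows(
      cx_rows,
      tibble::tibble(
        query = sample(seeds$gene, n_bg, replace = TRUE),
        partner = sample(truth$decoys, n_bg),
        mutual_rank = expansion_params()$coexpr_max_rank +
          sample(1:2000, n_bg)
      ),
      tibble::tibble(
        query = sample(truth$decoys, n_bg),
        partner = sample(rev(truth$decoys), n_bg),
        mutual_rank = sample(1:2000, n_bg)
      )
    ) |>
      dplyr::filter(.data$query != .data$partner) |>
      dplyr::distinct(.data$query, .data$partner, .keep_all = TRUE)
    pp_rows <- dplyr::bind_rows(
      pp_rows,
      tibble::tibble(
        a = sample(seeds$gene, n_bg, replace = TRUE),
        b = sample(truth$decoys, n_bg),
        score = round(stats::runif(n_bg, 0.01, 0.149), 3)
      )
    ) |>
      dplyr::distinct()

    all_genes <- c(seeds$gene, planted$gene, truth$decoys)
    id_map <- tibble::tibble(
      raw_id = sprintf("ACC%05d", seq_along(all_genes)),
      symbol = all_genes
    )

    list(
      tf_edges = tf_rows,
      gene_sets_a = dplyr::select(
        dplyr::filter(set_rows, .data$extract == "a"), -"extract"
      ),
      gene_sets_b = dplyr::select(
        dplyr::filter(set_rows, .data$extract == "b"), -"extract"
      ),
      coexpression = cx_rows,
      interactions = pp_rows,
      id_map = id_map,
      truth = truth
    )
  })
}

#' Generate synthetic topology annotations
#'
#' Planted secreted markers receive a signal peptide and zero transmembrane
#' segments; all other genes are spread over the remaining three topology
#' classes. The result round-trips through [write_phobius_short()] and
#' [read_phobius_short()]. Deterministic given `cfg$rng_seed`.
#'
#' @param truth Ground truth from [generate_knowledge_base()].
#' @param cfg The matching [synth_config()].
#' @return A topology annotation tibble.
#' @export
generate_topology <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$rng_seed + 1L, {
    planted <- truth$planted
    others <- c(truth$seeds$gene, planted$gene[!planted$secreted], truth$decoys)
    other_class <- sample(c("sp_and_tm", "tm_only", "neither"),
      length(others),
      replace = TRUE
    )
    tm_for <- function(cls) {
      ifelse(cls == "neither", 0L, sample(1:7, length(cls), replace = TRUE))
    }
    pred_for <- function(sp, tm) {
      dplyr::case_when(
        sp & tm == 0 ~ "n8-18c23/24o",
        sp & tm > 0 ~ paste0("n8-18c23/24o", tm * 10, "-", tm * 10 + 20, "i"),
        !sp & tm > 0 ~ paste0("i", tm, "-", tm + 21, "o"),
        TRUE ~ "o"
      )
    }
    ann <- dplyr::bind_rows(
      tibble::tibble(
        protein = planted$gene[planted$secreted],
        tm_count = 0L, signal_peptide = TRUE
      ),
      tibble::tibble(
        protein = others,
        tm_count = as.integer(tm_for(other_class)),
        signal_peptide = other_class == "sp_and_tm"
      )
    )
    dplyr::mutate(ann,
      prediction = pred_for(.data$signal_peptide, .data$tm_count)
    )
  })
}

#' Generate a synthetic paired expression matrix
#'
#' One probe per gene (synthetic `_at`-suffixed IDs). Baseline log2
#' intensities are Normal(8, 1) per gene; each tumor/normal pair shares a
#' pair-level offset Normal(0, `pair_sd`) (the matched-biopsy correlation a
#' paired test exploits); planted genes are shifted by +/- `effect_log2fc` in
#' tumor samples; measurement noise is Normal(0, `noise_sd`). Deterministic
#' given `cfg$rng_seed`.
#'
#' @param truth Ground truth from [generate_knowledge_base()].
#' @param cfg The matching [synth_config()].
#' @return A list with elements `es` (an [expression_set()]) and `probe_map`.
#' @export
generate_expression <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$rng_seed + 2L, {
    genes <- c(truth$seeds$gene, truth$planted$gene, truth$decoys)
    probes <- sprintf("SYN%04d_at", seq_along(genes))
    g <- length(genes)
    np <- cfg$n_pairs

    shift <- stats::setNames(rep(0, g), genes)
    shift[truth$planted$gene] <-
      ifelse(truth$planted$direction == "up", 1, -1) * cfg$effect_log2fc

    baseline <- stats::rnorm(g, mean = 8, sd = 1)
    pair_off <- matrix(stats::rnorm(g * np, 0, cfg$pair_sd), nrow = g)
    noise_t <- matrix(stats::rnorm(g * np, 0, cfg$noise_sd), nrow = g)
    noise_n <- matrix(stats::rnorm(g * np, 0, cfg$noise_sd), nrow = g)

    tumor <- baseline + pair_off + shift[genes] + noise_t
    normal <- baseline + pair_off + noise_n
    values <- cbind(tumor, normal)
    rownames(values) <- probes
    colnames(values) <- c(sprintf("T%02d", 1:np), sprintf("N%02d", 1:np))

    samples <- tibble::tibble(
      sample = colnames(values),
      condition = rep(c("tumor", "normal"), each = np),
      pair = rep(sprintf("P%02d", 1:np), 2)
    )
    list(
      es = expression_set(values, samples),
      probe_map = tibble::tibble(probe = probes, gene = genes)
    )
  })
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates the knowledge base, topology file and expression matrix for one
#' configuration and writes every file in the exact format the pipeline
#' readers consume. Each file carries a `# rng_seed: <seed>` comment header.
#' Running twice with the same configuration produces byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `paths` (named file paths) and `truth`.
#' @export
generate_bundle <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kb <- generate_knowledge_base(cfg)
  topo <- generate_topology(kb$truth, cfg)
  expr <- generate_expression(kb$truth, cfg)
  hdr <- paste0("rng_seed: ", cfg$rng_seed)
  p <- function(f) file.path(out_dir, f)

  paths <- c(
    tf_edges_a = p("tf_edges_a.tsv"), tf_edges_b = p("tf_edges_b.tsv"),
    gene_sets_a = p("gene_sets_a.gmt"), gene_sets_b = p("gene_sets_b.gmt"),
    coexpression = p("coexpression.tsv"), interactions = p("interactions.tsv"),
    id_map = p("id_map.tsv"), topology = p("topology.txt"),
    expression = p("expression.tsv"), samples = p("samples.tsv"),
    probe_map = p("probe_map.tsv"), seeds = p("seeds.tsv")
  )
  write_tf_edges(
    dplyr::filter(kb$tf_edges, .data$source_db == "tf_db_a"),
    paths["tf_edges_a"],
    comment = hdr
  )
  write_tf_edges(
    dplyr::filter(kb$tf_edges, .data$source_db == "tf_db_b"),
    paths["tf_edges_b"],
    comment = hdr
  )
  write_gene_sets(kb$gene_sets_a, paths["gene_sets_a"], comment = hdr)
  write_gene_sets(kb$gene_sets_b, paths["gene_sets_b"], comment = hdr)
  write_coexpression(kb$coexpression, paths["coexpression"], comment = hdr)
  write_interactions(kb$interactions, paths["interactions"], comment = hdr)
  write_id_map(kb$id_map, paths["id_map"], comment = hdr)
  write_phobius_short(topo, paths["topology"], comment = hdr)
  write_expression_matrix(
    expr$es, paths["expression"], paths["samples"],
    comment = hdr
  )
  writeLines(
    c(
      paste0("# ", hdr), "probe\tgene",
      paste(expr$probe_map$probe, expr$probe_map$gene, sep = "\t")
    ),
    paths["probe_map"]
  )
  writeLines(
    c(
      paste0("# ", hdr), "gene\tsubtype",
      paste(kb$truth$seeds$gene, kb$truth$seeds$subtype, sep = "\t")
    ),
    paths["seeds"]
  )
  invisible(list(paths = paths, truth = kb$truth))
}
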