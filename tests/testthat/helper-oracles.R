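# Independent oracles, deliberately written with plain loops and base R so
# they share no code path with the package implementation.

# Two-sided one-sample t-test p-value from first principles.
oracle_t_pvalue <- function(d) {
  n <- length(d)
  se <- sqrt(sum((d - mean(d))^2) / (n - 1)) / sqrt(n)
  tstat <- mean(d) / se
  2 * stats::pt(-abs(tstat), df = n - 1)
}

# Upper-tail hypergeometric P(X >= obs) by exhaustive enumeration of every
# possible query draw from the universe.
oracle_hyper_enum <- function(universe, term, query_size, obs) {
  draws <- utils::combn(universe, query_size)
  hits <- 0L
  for (j in seq_len(ncol(draws))) {
    if (length(intersect(draws[, j], term)) >= obs) hits <- hits + 1L
  }
  hits / ncol(draws)
}

# Per-gene predicate enumeration: a gene is predicted iff it is linked to at
# least one seed on every axis by at least one source.
oracle_predict <- function(genes, seeds, tf_edges, gene_sets, coexpr, inter,
                           max_rank = 2000, min_score = 0.150) {
  linked_tf <- function(g) {
    for (s in seeds) {
      for (i in seq_len(nrow(tf_edges))) {
        e <- tf_edges[i, ]
        # g regulates the seed
        if (e$tf == g && e$target == s) {
          return(TRUE)
        }
        # g is a target of a TF that regulates the seed
        if (e$target == g) {
          for (k in seq_len(nrow(tf_edges))) {
            if (tf_edges$tf[k] == e$tf && tf_edges$target[k] == s) {
              return(TRUE)
            }
          }
        }
        # g is a direct target of the seed acting as a TF
        if (e$tf == s && e$target == g) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  linked_pw <- function(g) {
    ok_ns <- c("molecular_function", "biological_process", "pathway")
    for (s in seeds) {
      sets_s <- unique(gene_sets$set_id[gene_sets$gene == s &
        gene_sets$namespace %in% ok_ns])
      for (id in sets_s) {
        members <- gene_sets$gene[gene_sets$set_id == id &
          gene_sets$namespace %in% ok_ns]
        if (g %in% members) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  linked_cx <- function(g) {
    for (s in seeds) {
      for (i in seq_len(nrow(coexpr))) {
        if (coexpr$query[i] == s && coexpr$partner[i] == g &&
          coexpr$mutual_rank[i] <= max_rank) {
          return(TRUE)
        }
      }
      for (i in seq_len(nrow(inter))) {
        pair <- c(inter$a[i], inter$b[i])
        if (s %in% pair && g %in% setdiff(pair, s) &&
          inter$score[i] >= min_score) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  out <- character()
  for (g in genes) {
    if (linked_tf(g) && linked_pw(g) && linked_cx(g)) out <- c(out, g)
  }
  sort(out)
}

# Small random knowledge base over <= n_genes genes for oracle-equivalence
# checks; uses its own RNG draws only.
random_small_kb <- function(n_genes = 30, n_seeds = 3) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  seeds <- sample(genes, n_seeds)
  n_tf_edges <- sample(10:25, 1)
  tf_edges <- tibble::tibble(
    tf = sample(genes, n_tf_edges, replace = TRUE),
    target = sample(genes, n_tf_edges, replace = TRUE),
    mode = sample(c("activation", "repression", "unknown"), n_tf_edges,
      replace = TRUE
    ),
    source_db = sample(c("db1", "db2"), n_tf_edges, replace = TRUE)
  )
  tf_edges <- tf_edges[tf_edges$tf != tf_edges$target, ]
  n_sets <- sample(3:6, 1)
  gene_sets <- purrr::map_dfr(seq_len(n_sets), function(i) {
    tibble::tibble(
      set_id = sprintf("S%02d", i),
      name = paste("set", i),
      namespace = sample(
        c("biological_process", "molecular_function", "pathway",
          "cellular_component"), 1
      ),
      gene = sample(genes, sample(2:6, 1))
    )
  })
  n_cx <- sample(8:20, 1)
  coexpr <- tibble::tibble(
    query = sample(genes, n_cx, replace = TRUE),
    partner = sample(genes, n_cx, replace = TRUE),
    mutual_rank = sample(c(1:50, 2500:2600), n_cx, replace = TRUE)
  )
  coexpr <- dplyr::distinct(
    coexpr[coexpr$query != coexpr$partner, ],
    query, partner,
    .keep_all = TRUE
  )
  n_pp <- sample(8:20, 1)
  inter <- tibble::tibble(
    a = sample(genes, n_pp, replace = TRUE),
    b = sample(genes, n_pp, replace = TRUE),
    score = round(stats::runif(n_pp, 0, 1), 3)
  )
  inter <- dplyr::distinct(inter[inter$a != inter$b, ])
  list(
    genes = genes, seeds = seeds, tf_edges = tf_edges,
    gene_sets = gene_sets, coexpr = coexpr, inter = inter
  )
}

# Run the package's expand/intersect route on a random_small_kb.
pipeline_predict <- function(kb, subtype = "basal") {
  tf_pool <- expand_tf(kb$seeds, kb$tf_edges, subtype = subtype)
  pw_pool <- expand_pathway(kb$seeds, kb$gene_sets, subtype = subtype)
  cx_pool <- expand_coexpression(kb$seeds, kb$coexpr, kb$inter,
    subtype = subtype
  )
  intersect_axes(tf_pool, pw_pool, cx_pool)
}
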