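edges_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    tf = purrr::map_chr(rows, 1),
    target = purrr::map_chr(rows, 2),
    mode = "unknown",
    source_db = purrr::map_chr(rows, ~ if (length(.x) >= 3) .x[[3]] else "db1")
  )
}

sets_tbl <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      set_id = r$id, name = r$id,
      namespace = if (is.null(r$ns)) "biological_process" else r$ns,
      gene = r$members
    )
  })
}

test_that("default seed configuration has the canonical subtype panel sizes", {
  seeds <- seed_markers()
  expect_equal(
    dplyr::count(seeds, subtype) |> tibble::deframe(),
    c(basal = 8, her2 = 2, luminal = 13)
  )
  expect_false(anyDuplicated(seeds$gene) > 0)
  shipped <- read_seed_markers(
    system.file("extdata", "seed_markers.tsv", package = "markermine")
  )
  expect_equal(dplyr::arrange(shipped, gene), dplyr::arrange(seeds, gene))
})

test_that("TF expansion collects regulators, co-targets, and seed targets", {
  # TF1 regulates the seed and G2: both TF1 and G2 enter the pool
  pool <- expand_tf("S", edges_tbl(list("TF1", "S"), list("TF1", "G2")))
  expect_setequal(pool$genes, c("TF1", "G2", "S"))
  expect_true(all(
    pool$evidence$relation[pool$evidence$candidate == "S"] == "self-target"
  ))

  # a seed that is itself a TF contributes its own targets
  pool <- expand_tf("S", edges_tbl(list("S", "G3")))
  expect_setequal(pool$genes, "G3")

  # no edges: empty pool, absent seeds only logged
  suppressMessages(pool <- expand_tf("S", edges_tbl(list("TF1", "X"))[0, ]))
  expect_length(pool$genes, 0)
})

test_that("pathway expansion unions co-members and ignores cellular components", {
  sets <- sets_tbl(
    list(id = "P1", members = c("S", "G4", "G5")),
    list(id = "CC1", ns = "cellular_component", members = c("S", "G9"))
  )
  pool <- expand_pathway("S", sets)
  expect_setequal(pool$genes, c("S", "G4", "G5"))
  expect_false("G9" %in% pool$genes)
  expect_length(expand_pathway("ABSENT", sets)$genes, 0)
})

test_that("co-expression expansion applies rank, score, and partner-cap rules", {
  cx <- tibble::tibble(
    query = c("S", "S"), partner = c("A", "B"), mutual_rank = c(1, 2001)
  )
  inter <- tibble::tibble(a = "S", b = "C", score = 0.149)
  pool <- expand_coexpression("S", cx, inter)
  expect_setequal(pool$genes, "A") # B beyond rank 2000, C below 0.150

  # exactly 0.150 is included
  inter2 <- tibble::tibble(a = "S", b = "C", score = 0.150)
  expect_setequal(expand_coexpression("S", cx[0, ], inter2)$genes, "C")

  # 150 eligible partners: exactly the 100 highest scores survive
  many <- tibble::tibble(
    a = "S", b = sprintf("P%03d", 1:150),
    score = seq(0.95, 0.2, length.out = 150)
  )
  pool <- expand_coexpression("S", cx[0, ], many)
  expect_length(pool$genes, 100)
  expect_setequal(pool$genes, sprintf("P%03d", 1:100))

  # ties at the cap break lexicographically by partner symbol
  tied <- tibble::tibble(a = "S", b = c("ZZ", "AA", "MM"), score = 0.5)
  pool <- expand_coexpression(
    "S", cx[0, ], tied,
    params = expansion_params(interaction_max_partners = 2)
  )
  expect_equal(pool$genes, c("AA", "MM"))
})

test_that("union within an axis is binary; intersection across axes is strict", {
  e1 <- expand_tf("S", edges_tbl(list("TF1", "S"), list("TF1", "G1")))
  e2 <- expand_tf("S", edges_tbl(list("TF2", "S"), list("TF2", "G2"), list("TF1", "S")))
  both <- combine_sources(e1, e2)
  expect_setequal(both$genes, c("TF1", "TF2", "G1", "G2", "S"))
  # a gene found by both sources appears once but keeps both evidence trails
  dup <- combine_sources(e1, e1)
  expect_equal(dup$genes, e1$genes)

  mismatched <- expand_pathway("S", sets_tbl(list(id = "P", members = c("S", "X"))))
  expect_error(combine_sources(e1, mismatched), "identical axis")

  mk <- function(axis, genes, subtype = "basal") {
    markermine:::new_axis_pool(subtype, axis, tibble::tibble(
      candidate = genes, seed = "S", axis = axis,
      source_db = "db", relation = "r"
    ))
  }
  expect_equal(
    intersect_axes(
      mk("tf", c("A", "B")), mk("pathway", c("B", "C")),
      mk("coexpression", c("B", "D"))
    ),
    "B"
  )
  # present on two axes only: excluded
  expect_length(
    intersect_axes(
      mk("tf", "A"), mk("pathway", "A"), mk("coexpression", "Z")
    ),
    0
  )
  expect_error(
    intersect_axes(mk("tf", "A"), mk("pathway", "A"), mk("coexpression", "A", "luminal")),
    "one subtype"
  )
})

test_that("subtype partition labels genes with every run that produced them", {
  part <- partition_subtypes(list(
    basal = c("X", "Y"), luminal = "X", her2 = "X"
  ))
  expect_equal(part$subtypes[part$gene == "X"][[1]], c("basal", "luminal", "her2"))
  expect_equal(part$subtypes[part$gene == "Y"][[1]], "basal")
  expect_equal(nrow(partition_subtypes(list(basal = character()))), 0)

  regions <- venn_regions(part)
  expect_equal(regions$`basal&luminal&her2`, "X")
  expect_equal(regions$basal, "Y")
  # regions are disjoint and cover the predictions
  expect_equal(sort(unlist(regions, use.names = FALSE)), sort(part$gene))
})

test_that("expansion matches per-gene predicate enumeration on random knowledge bases", {
  withr::local_seed(42)
  for (i in 1:30) {
    kb <- random_small_kb(n_genes = sample(10:50, 1))
    got <- pipeline_predict(kb)
    want <- oracle_predict(
      kb$genes, kb$seeds, kb$tf_edges, kb$gene_sets, kb$coexpr, kb$inter
    )
    expect_equal(intersect(got, kb$genes), want)
    # pool candidates outside the declared universe can only be TFs
    expect_true(all(got %in% c(kb$genes, kb$tf_edges$tf)))
  }
})

test_that("adding knowledge rows never shrinks pools; duplication changes nothing", {
  withr::local_seed(99)
  kb <- random_small_kb(n_genes = 30)
  base <- pipeline_predict(kb)

  # duplicating evidence rows (binary weights) leaves the result unchanged
  kb_dup <- kb
  kb_dup$tf_edges <- dplyr::bind_rows(kb$tf_edges, kb$tf_edges[1, ])
  kb_dup$gene_sets <- dplyr::bind_rows(kb$gene_sets, kb$gene_sets[1, ])
  expect_equal(pipeline_predict(kb_dup), base)

  # adding a row can only grow pools and the intersection
  for (i in 1:10) {
    kb_plus <- kb
    kb_plus$tf_edges <- dplyr::bind_rows(
      kb$tf_edges,
      tibble::tibble(
        tf = sample(kb$genes, 1), target = sample(kb$genes, 1),
        mode = "unknown", source_db = "db1"
      )
    )
    expect_true(all(base %in% pipeline_predict(kb_plus)))
  }
})

test_that("subtype runs are order-independent", {
  cfg <- synth_config(rng_seed = 5, decoy_axis_dropout = 0.5)
  kb <- generate_knowledge_base(cfg)
  run_order <- function(order) {
    res <- lapply(order, function(st) {
      seeds <- kb$truth$seeds$gene[kb$truth$seeds$subtype == st]
      kbx <- list(
        genes = character(), seeds = seeds, tf_edges = kb$tf_edges,
        gene_sets = dplyr::bind_rows(kb$gene_sets_a, kb$gene_sets_b),
        coexpr = kb$coexpression, inter = kb$interactions
      )
      pipeline_predict(kbx, subtype = st)
    })
    names(res) <- order
    res[sort(order)]
  }
  expect_equal(
    run_order(c("basal", "luminal", "her2")),
    run_order(c("her2", "basal", "luminal"))
  )
})
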