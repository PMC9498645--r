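test_that("config validation rejects infeasible studies", {
  expect_error(
    synth_config(n_genes = 20, n_planted_markers = 10),
    "infeasible"
  )
  expect_s3_class(synth_config(), "synth_config")
})

test_that("planted markers are linked to a same-subtype seed on every axis", {
  cfg <- synth_config(rng_seed = 21)
  kb <- generate_knowledge_base(cfg)
  sets <- dplyr::bind_rows(kb$gene_sets_a, kb$gene_sets_b)
  params <- expansion_params()
  for (i in seq_len(nrow(kb$truth$planted))) {
    g <- kb$truth$planted$gene[i]
    st <- kb$truth$planted$subtype[i]
    seeds <- kb$truth$seeds$gene[kb$truth$seeds$subtype == st]
    found <- oracle_predict(
      g, seeds, kb$tf_edges, sets, kb$coexpression, kb$interactions,
      max_rank = params$coexpr_max_rank,
      min_score = params$interaction_min_score
    )
    expect_equal(found, g)
  }
})

test_that("with full decoy dropout no decoy touches a seed on any axis", {
  cfg <- synth_config(rng_seed = 3, decoy_axis_dropout = 1.0)
  kb <- generate_knowledge_base(cfg)
  sets <- dplyr::bind_rows(kb$gene_sets_a, kb$gene_sets_b)
  all_seeds <- kb$truth$seeds$gene
  found <- oracle_predict(
    kb$truth$decoys, all_seeds, kb$tf_edges, sets,
    kb$coexpression, kb$interactions
  )
  expect_length(found, 0)
})

test_that("zero dropout reconnects decoys so recovery grows beyond the planted set", {
  cfg <- synth_config(rng_seed = 13, decoy_axis_dropout = 0.0, n_genes = 60)
  kb <- generate_knowledge_base(cfg)
  sets <- dplyr::bind_rows(kb$gene_sets_a, kb$gene_sets_b)
  recovered <- unlist(lapply(markermine:::SUBTYPES, function(st) {
    kbx <- list(
      seeds = kb$truth$seeds$gene[kb$truth$seeds$subtype == st],
      tf_edges = kb$tf_edges, gene_sets = sets,
      coexpr = kb$coexpression, inter = kb$interactions
    )
    suppressMessages(pipeline_predict(kbx, subtype = st))
  }))
  expect_true(any(kb$truth$decoys %in% recovered))
})

test_that("generated files are byte-identical across reruns with one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- synth_config(rng_seed = 8)
  b1 <- generate_bundle(cfg, d1)
  b2 <- generate_bundle(cfg, d2)
  for (nm in names(b1$paths)) {
    expect_identical(
      readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
      info = nm
    )
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  b3 <- generate_bundle(synth_config(rng_seed = 9), d3)
  expect_false(identical(
    readLines(b1$paths[["expression"]]), readLines(b3$paths[["expression"]])
  ))
})

test_that("every generated file round-trips through the pipeline readers", {
  d <- withr::local_tempdir()
  cfg <- synth_config(rng_seed = 15)
  bundle <- generate_bundle(cfg, d)
  kb <- generate_knowledge_base(cfg)
  p <- bundle$paths

  edges_a <- read_tf_edges(p[["tf_edges_a"]], source_db = "tf_db_a")
  edges_b <- read_tf_edges(p[["tf_edges_b"]], source_db = "tf_db_b")
  expect_equal(
    dplyr::arrange(dplyr::bind_rows(edges_a, edges_b), tf, target, source_db),
    dplyr::arrange(kb$tf_edges, tf, target, source_db)
  )
  expect_equal(
    dplyr::arrange(read_gene_sets(p[["gene_sets_a"]]), set_id, gene),
    dplyr::arrange(kb$gene_sets_a, set_id, gene)
  )
  expect_equal(read_coexpression(p[["coexpression"]]), kb$coexpression)
  expect_equal(read_interactions(p[["interactions"]]), kb$interactions)
  expect_equal(read_id_map(p[["id_map"]]), kb$id_map)

  topo <- generate_topology(kb$truth, cfg)
  reread <- read_phobius_short(p[["topology"]])
  expect_equal(
    reread[, c("protein", "tm_count", "signal_peptide")],
    topo[, c("protein", "tm_count", "signal_peptide")]
  )
  # planted secreted markers carry SP = Y, TM = 0
  planted_secreted <- kb$truth$planted$gene[kb$truth$planted$secreted]
  rows <- reread[reread$protein %in% planted_secreted, ]
  expect_true(all(rows$signal_peptide & rows$tm_count == 0))

  expr <- generate_expression(kb$truth, cfg)
  es <- read_expression_matrix(p[["expression"]], p[["samples"]])
  expect_equal(es$values, expr$es$values, tolerance = 1e-8)
  expect_equal(es$samples, expr$es$samples)
  expect_equal(read_probe_map(p[["probe_map"]]), expr$probe_map)
  expect_equal(read_seed_markers(p[["seeds"]]), kb$truth$seeds)
})

test_that("an empty truth yields a parseable header-only topology file", {
  cfg <- synth_config(rng_seed = 4)
  truth <- markermine:::synth_truth(cfg)
  truth$planted <- truth$planted[0, ]
  truth$seeds <- truth$seeds[0, ]
  truth$decoys <- character()
  topo <- generate_topology(truth, cfg)
  expect_equal(nrow(topo), 0)
  f <- withr::local_tempfile(fileext = ".txt")
  write_phobius_short(topo, f)
  expect_equal(nrow(read_phobius_short(f)), 0)
})
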