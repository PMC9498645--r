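# A tiny paired expression set built directly from a matrix of within-pair
# structure: tumor value = normal value + delta per probe.
make_es <- function(normal, delta) {
  n <- ncol(normal)
  tumor <- normal + delta
  values <- cbind(tumor, normal)
  colnames(values) <- c(sprintf("T%02d", 1:n), sprintf("N%02d", 1:n))
  expression_set(values, tibble::tibble(
    sample = colnames(values),
    condition = rep(c("tumor", "normal"), each = n),
    pair = rep(sprintf("P%02d", 1:n), 2)
  ))
}

test_that("expression_set validates pairing and finiteness", {
  m <- matrix(rnorm(20), 2, 10,
    dimnames = list(c("p1", "p2"), sprintf("S%02d", 1:10))
  )
  sheet <- tibble::tibble(
    sample = colnames(m),
    condition = rep(c("tumor", "normal"), each = 5),
    pair = c(paste0("P", 1:5), paste0("P", 1:5))
  )
  expect_s3_class(expression_set(m, sheet), "expression_set")

  bad <- sheet
  bad$pair[6] <- "P9" # normal P9 has no tumor partner
  expect_error(expression_set(m, bad), "bijective")

  m2 <- m
  m2[1, 1] <- NA
  expect_error(expression_set(m2, sheet), "finite")
})

test_that("paired t-test matches a from-scratch t statistic and CDF", {
  withr::local_seed(314)
  normal <- matrix(rnorm(50 * 10, 8, 1), 50, 10,
    dimnames = list(sprintf("p%02d", 1:50), NULL)
  )
  delta <- matrix(rnorm(50 * 10, mean = 2, sd = 0.5), 50, 10,
    dimnames = dimnames(normal)
  )
  es <- make_es(normal, delta)
  for (probe in sample(rownames(normal), 10)) {
    res <- paired_de_test(es, probe)
    expect_equal(res$p_value, oracle_t_pvalue(delta[probe, ]), tolerance = 1e-9)
    expect_equal(res$mean_log2_diff, mean(delta[probe, ]), tolerance = 1e-12)
    expect_equal(res$n_pairs, 10L)
  }
})

test_that("degenerate and null paired inputs are handled explicitly", {
  normal <- matrix(8, 1, 10, dimnames = list("p1", NULL))

  null_es <- make_es(normal, matrix(0, 1, 10))
  res <- paired_de_test(null_es, "p1")
  expect_equal(res$direction, "ns")
  expect_equal(res$mean_log2_diff, 0)
  expect_equal(res$p_value, 1)

  const_es <- make_es(normal, matrix(1, 1, 10))
  res <- paired_de_test(const_es, "p1")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  expect_equal(res$direction, "up")

  tiny <- expression_set(
    matrix(c(1, 2), 1, 2, dimnames = list("p1", c("T1", "N1"))),
    tibble::tibble(
      sample = c("T1", "N1"), condition = c("tumor", "normal"), pair = "P1"
    )
  )
  expect_error(paired_de_test(tiny, "p1"), "at least 2")
})

test_that("swapping tumor and normal labels flips directions, keeps p-values", {
  withr::local_seed(2718)
  normal <- matrix(rnorm(30 * 10, 8, 1), 30, 10,
    dimnames = list(sprintf("p%02d", 1:30), NULL)
  )
  delta <- matrix(rnorm(30 * 10, 0, 1), 30, 10)
  delta[1:10, ] <- delta[1:10, ] + 2
  es <- make_es(normal, delta)
  es_swap <- es
  es_swap$samples$condition <- ifelse(
    es$samples$condition == "tumor", "normal", "tumor"
  )
  flip <- c(up = "down", down = "up", ns = "ns")
  for (probe in rownames(normal)) {
    a <- paired_de_test(es, probe)
    b <- paired_de_test(es_swap, probe)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
    expect_equal(b$direction, unname(flip[a$direction]))
    expect_equal(b$mean_log2_diff, -a$mean_log2_diff, tolerance = 1e-12)
  }
})

test_that("confidence interval matches the independent textbook computation", {
  v <- c(0, 0, 0, 0, 2, 2, 2, 2)
  ci <- confidence_interval(v, level = 0.05)
  oracle <- stats::t.test(v, conf.level = 0.95)$conf.int
  expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-9)

  expect_equal(unname(confidence_interval(rep(3, 5))), c(3, 3))
  expect_error(confidence_interval(v, level = 0), "between 0 and 1")
  expect_error(confidence_interval(v, level = 1), "between 0 and 1")
  expect_error(confidence_interval(1), "at least 2")
})

test_that("multi-probe genes are represented by their smallest-p probe", {
  withr::local_seed(7)
  normal <- matrix(rnorm(3 * 10, 8, 1), 3, 10,
    dimnames = list(c("pa", "pb", "pc"), NULL)
  )
  delta <- rbind(
    rnorm(10, 2, 0.5), # strong probe for GENE1
    rnorm(10, 0, 0.5), # weak probe for GENE1
    rnorm(10, -2, 0.5) # GENE2
  )
  es <- make_es(normal, delta)
  pm <- tibble::tibble(probe = c("pa", "pb", "pc"), gene = c("GENE1", "GENE1", "GENE2"))
  pred <- tibble::tibble(
    gene = c("GENE1", "GENE2", "GENE3"),
    subtype = c("basal", "basal", "luminal")
  )
  suppressMessages(val <- validate_markers(pred, es, pm))
  expect_equal(val$results$probe[val$results$gene == "GENE1"], "pa")
  expect_equal(val$missing, "GENE3")
  tly <- val$tally
  expect_equal(tly$missing[tly$subtype == "luminal"], 1L)
  # conservation: classes sum to the number of predictions per subtype
  expect_equal(tly$up + tly$down + tly$ns + tly$missing, tly$n)
})

test_that("tallies count multi-subtype genes once per subtype and once overall", {
  calls <- tibble::tibble(
    gene = c("A", "A", "B"),
    subtype = c("basal", "luminal", "basal"),
    direction = c("up", "up", "down")
  )
  tly <- tally_markers(calls)
  expect_equal(tly$up[tly$subtype == "basal"], 1L)
  expect_equal(tly$up[tly$subtype == "luminal"], 1L)
  expect_equal(tly$up[tly$subtype == "total"], 1L)
  expect_equal(tly$down[tly$subtype == "total"], 1L)

  empty <- tally_markers(calls[0, ])
  expect_equal(empty$n[empty$subtype == "total"], 0L)
})

test_that("planted effects are recovered in direction with high power", {
  # 2 log2-unit shifts at noise sd 0.5 with 10 pairs: essentially always
  # called in the right direction; nulls stay non-significant at ~alpha rate
  withr::local_seed(1234)
  n_rep <- 40
  correct <- 0L
  null_sig <- 0L
  n_null <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- synth_config(n_genes = 40, rng_seed = 1000 + r)
    truth <- markermine:::synth_truth(cfg)
    expr <- generate_expression(truth, cfg)
    for (i in seq_len(nrow(truth$planted))) {
      probe <- expr$probe_map$probe[expr$probe_map$gene == truth$planted$gene[i]]
      res <- paired_de_test(expr$es, probe)
      correct <- correct + (res$direction == truth$planted$direction[i])
    }
    null_probes <- expr$probe_map$probe[expr$probe_map$gene %in% truth$decoys]
    for (probe in null_probes) {
      n_null <- n_null + 1L
      res <- paired_de_test(expr$es, probe)
      null_sig <- null_sig + (res$direction != "ns")
    }
  }
  expect_gte(correct / (n_rep * 12), 0.95)
  expect_gte(1 - null_sig / n_null, 0.90)
})
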