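test_that("ssGSEA reproduces the direct-summation values on a 4-gene sample", {
  m <- toy_expr(cbind(s1 = c(5, 3, 2, 1)), genes = c("TOP", "B", "C", "BOT"))
  for (a in c(0, 0.25, 1)) {
    es_top <- ssgsea(m, gene_set_collection(list(s = "TOP")),
                     alpha = a, normalize = FALSE)
    expect_equal(unname(es_top[1, 1]), 2)       # 1 + 2/3 + 1/3 + 0
    es_bot <- ssgsea(m, gene_set_collection(list(s = "BOT")),
                     alpha = a, normalize = FALSE)
    expect_equal(unname(es_bot[1, 1]), -2)
  }
  # independent direct-summation oracle on a random instance
  set.seed(4)
  x <- runif(12)
  mask <- seq_len(12) %in% sample(12, 4)
  mm <- toy_expr(cbind(s = x), genes = paste0("g", 1:12))
  es <- ssgsea(mm, gene_set_collection(list(s = paste0("g", which(mask)))),
               alpha = 0.25, normalize = FALSE)
  expect_equal(unname(es[1, 1]), oracle_ssgsea_es(x, mask, 0.25))
})

test_that("ssGSEA is rank-invariant and validates set overlap", {
  set.seed(8)
  m <- toy_expr(matrix(runif(40 * 3, 0, 8), 40))
  sets <- gene_set_collection(list(a = rownames(m)[1:5], b = rownames(m)[6:20]))
  base <- ssgsea(m, sets)
  shifted <- ssgsea(toy_expr(unclass(m) + 100), sets)
  expect_identical(unclass(base), unclass(shifted))
  mono <- ssgsea(toy_expr(exp(unclass(m))), sets)
  expect_identical(unclass(base), unclass(mono))

  expect_warning(ssgsea(m, gene_set_collection(list(a = rownames(m)[1:3],
                                                    none = "ZZZ"))),
                 "zero overlap")
  expect_error(ssgsea(m, gene_set_collection(list(all = rownames(m)))),
               "every gene")
})

test_that("random gene sets have near-zero mean enrichment", {
  set.seed(0)
  m <- toy_expr(matrix(runif(200, 0, 10), 200, 1))
  sets <- gene_set_collection(stats::setNames(
    lapply(seq_len(500), function(i) sample(rownames(m), 20)),
    paste0("rnd", seq_len(500))))
  # the unweighted walk (alpha = 0) is a tied-down random walk for a
  # random set, so its mean enrichment vanishes; rank weighting (alpha
  # > 0) adds a small systematic positive offset by construction
  es <- ssgsea(m, sets, alpha = 0, normalize = TRUE)
  expect_lt(abs(mean(es)), 0.05)
})

test_that("estimate scores are the two signature enrichments and their sum", {
  set.seed(5)
  m <- toy_expr(matrix(runif(60 * 3, 0, 8), 60))
  str_g <- rownames(m)[1:10]; imm_g <- rownames(m)[11:20]
  es <- estimate_scores(m, str_g, imm_g)
  expect_equal(es$estimate, es$stromal + es$immune)
  sw <- estimate_scores(m, imm_g, str_g)
  expect_equal(sw$stromal, es$immune)
  expect_equal(sw$immune, es$stromal)

  # a sample overexpressing only immune genes tops the immune score
  base <- matrix(5, 30, 3, dimnames = list(paste0("g", 1:30), c("a", "b", "hot")))
  base <- base + matrix(runif(90, -0.5, 0.5), 30)
  base[1:8, "hot"] <- base[1:8, "hot"] + 10
  mh <- toy_expr(base)
  eh <- estimate_scores(mh, rownames(mh)[20:28], rownames(mh)[1:8])
  expect_equal(which.max(eh$immune), 3L)
})

test_that("preranked GSEA attains ES = 1 for a top-block set and is reproducible", {
  r <- c(a = 6, b = 5, c = 4, d = 3, e = 2, f = 1)
  sets <- gene_set_collection(list(top2 = c("a", "b"), bottom2 = c("e", "f")))
  res <- gsea_preranked(r, sets, n_perm = 200, seed = 1)
  expect_equal(res$ES[res$set == "top2"], 1)    # running sum peaks at position 2
  expect_equal(res$ES[res$set == "bottom2"], -1)
  res2 <- gsea_preranked(r, sets, n_perm = 200, seed = 1)
  expect_identical(res$p_value, res2$p_value)
  expect_true(all(res$padj >= res$p_value - 1e-15))

  expect_warning(gsea_preranked(r, gene_set_collection(
    list(top2 = c("a", "b"), tiny = "a")), n_perm = 200, seed = 1),
    "overlap < 2")
})

test_that("preranked ES agrees with the reference running-sum implementation", {
  set.seed(3)
  r <- sort(rnorm(60), decreasing = TRUE)
  names(r) <- paste0("g", seq_along(r))
  idx <- sort(sample(60, 8))
  ours <- gsea_preranked(r, gene_set_collection(list(s = names(r)[idx])),
                         n_perm = 100, seed = 1)$ES
  ref <- fgsea::calcGseaStat(r, selectedStats = idx, gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("preranked p-values are calibrated for random sets", {
  set.seed(0)
  r <- rnorm(150)
  names(r) <- paste0("g", seq_along(r))
  ps <- vapply(seq_len(200), function(i) {
    g <- sample(names(r), 10)
    gsea_preranked(r, gene_set_collection(list(s = g)),
                   n_perm = 100, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("differential expression is exact on identical groups and recovers planted shifts", {
  de0 <- differential_expression(
    toy_expr(cbind(a = c(1, 2), b = c(3, 4), c = c(1, 2), d = c(3, 4))),
    c("x", "x", "y", "y"))
  expect_equal(de0$log2FC, c(0, 0))
  expect_equal(de0$p_value, c(1, 1))

  cfg <- small_sim(seed = 0)
  bulk <- simulate_bulk_cohort(cfg)
  strat <- ifelse(bulk$truth$ne_fraction > median(bulk$truth$ne_fraction),
                  "high", "low")
  de <- differential_expression(bulk$expr, factor(strat, c("low", "high")))
  planted <- attr(bulk$truth, "signature_genes")
  hit <- de$gene[de$fdr < 0.05]
  expect_gte(mean(planted %in% hit), 0.9)
  top <- top_k_export(de, k = 60)
  expect_gte(mean(planted %in% top$up), 0.9)   # NE signature rises with f
})

test_that("top-k export orders by t and validates k", {
  de <- data.frame(gene = c("a", "b", "c"), log2FC = 0, t = c(2, -1, 5),
                   p_value = 0.5, fdr = 0.5)
  ex <- top_k_export(de, 1)
  expect_identical(ex$up, "c")
  expect_identical(ex$down, "b")
  expect_error(top_k_export(de, 4), "exceeds")
})
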