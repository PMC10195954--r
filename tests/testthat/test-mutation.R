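test_that("TMB divides variant counts by 38 Mb and is additive", {
  maf <- toy_maf(sample = rep(c("A", "B"), c(38, 76)),
                 gene = paste0("g", 1:114))
  expect_equal(tmb(maf, "A"), 1.0)
  expect_equal(tmb(maf, "B"), 2.0)
  expect_error(tmb(maf, "nope"), "not present")

  # concatenating two MAFs sums counts exactly
  both <- maf_table(rbind(maf, maf))
  expect_equal(tmb(both, "A"), 2 * tmb(maf, "A"))

  all_ <- tmb_all(maf)
  expect_equal(all_$tmb[all_$sample == "B"], 2.0)
})

test_that("silent variants can be excluded from the burden", {
  maf <- toy_maf(sample = rep("A", 4), gene = paste0("g", 1:4),
                 vclass = c("Missense_Mutation", "Silent", "Silent",
                            "Nonsense_Mutation"))
  expect_equal(tmb(maf, "A") * 38, 4)
  expect_equal(tmb(maf, "A", exclude_silent = TRUE) * 38, 2)
})

test_that("substitutions collapse to pyrimidine-reference classes with Ti/Tv conservation", {
  maf <- toy_maf(sample = rep("A", 4), gene = paste0("g", 1:4),
                 ref = c("G", "A", "C", "T"), alt = c("T", "G", "T", "G"))
  sc <- snv_classes(maf)
  # G>T complements to C>A (Tv); A>G complements to T>C (Ti)
  expect_equal(unname(sc$counts[c("C>A", "T>C", "C>T", "T>G")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sc$ti + sc$tv, sum(sc$counts))
  expect_equal(sc$ti, 2L)
  expect_equal(sc$per_sample$ti_frac + sc$per_sample$tv_frac, 1)

  bad <- toy_maf(sample = c("A", "A"), gene = c("g1", "g2"),
                 ref = c("C", "C"), alt = c("C", "A"))
  expect_warning(sc2 <- snv_classes(bad), "ref == alt")
  expect_equal(sum(sc2$counts), 1L)
})

test_that("class counts conserve the SNP total on simulated data", {
  bulk <- simulate_bulk_cohort(small_sim(seed = 3))
  sc <- snv_classes(bulk$maf)
  expect_equal(sum(sc$counts), sum(bulk$maf$Variant_Type == "SNP"))
})

test_that("Fisher 2x2 matches hand-enumerated hypergeometric values", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, 2 / 252)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)$p_value, 2 / choose(20, 10))
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")

  # cross-product odds ratio, 0.5 continuity only with a zero cell
  expect_equal(fisher_exact_2x2(2, 4, 1, 8)$odds_ratio, 4)
  expect_equal(fisher_exact_2x2(3, 0, 1, 5)$odds_ratio,
               (3.5 * 5.5) / (0.5 * 1.5))

  # spot-check the enumeration oracle against random tables
  set.seed(6)
  for (i in 1:25) {
    tb <- rpois(4, 3)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p_value,
                 oracle_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
})

test_that("differential mutation flags the planted pattern and skips unmutated genes", {
  samples <- paste0("P", 1:20)
  groups <- setNames(rep(c("grpA", "grpB"), each = 10), samples)
  maf <- toy_maf(sample = c(samples[1:10], samples),
                 gene = c(rep("DIFF", 10), rep("FLAT", 20)))
  res <- differential_mutation(maf, groups)
  diff_row <- res[res$gene == "DIFF", ]
  expect_true(diff_row$flagged)
  expect_equal(diff_row$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_false(res[res$gene == "FLAT", ]$flagged)
  expect_false("NEVER" %in% res$gene)
})

test_that("planted differentially mutated genes are recovered on simulated cohorts", {
  bulk <- simulate_bulk_cohort(small_sim(seed = 0))
  f <- bulk$truth$ne_fraction
  groups <- setNames(ifelse(f > median(f), "high", "low"), bulk$truth$sample)
  res <- differential_mutation(bulk$maf, groups)
  planted <- attr(bulk$truth, "diff_mut_genes")
  expect_gte(mean(planted %in% res$gene[res$flagged]), 0.9)
})

test_that("pairwise interactions label co-occurrence and exclusivity", {
  samples <- paste0("P", 1:20)
  # co-mutated pair in 10/20, never alone; exclusive pair covering the rest
  maf <- toy_maf(
    sample = c(rep(samples[1:10], 2), samples[11:15], samples[16:20]),
    gene = c(rep("CO1", 10), rep("CO2", 10), rep("EX1", 5), rep("EX2", 5)))
  res <- interactions(maf, top_n = 4)
  co <- res[res$gene1 %in% c("CO1", "CO2") & res$gene2 %in% c("CO1", "CO2"), ]
  expect_equal(co$label, "co_occurrence")
  expect_equal(co$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  ex <- res[res$gene1 %in% c("EX1", "EX2") & res$gene2 %in% c("EX1", "EX2"), ]
  expect_equal(ex$label, "exclusivity")
  expect_lt(ex$odds_ratio, 1)
  # no self pairs; cap with warning
  expect_false(any(res$gene1 == res$gene2))
  expect_warning(interactions(maf, top_n = 10), "capped")
})

test_that("MAF validation catches structural problems", {
  expect_error(maf_table(data.frame(Hugo_Symbol = "g")), "missing column")
  expect_error(toy_maf("A", "g", ref = "CT", alt = "A", vtype = "SNP"),
               "single-base")
  rt <- tempfile(fileext = ".maf")
  maf <- toy_maf(c("A", "B"), c("g1", "g2"))
  write_maf(maf, rt)
  expect_equal(nrow(read_maf(rt)), 2L)
})
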