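test_that("mutation binarization is idempotent and handles missing sequencing", {
  muts <- tibble::tibble(sample_id = c("S1", "S1"), gene = c("TP53", "TP53"),
                         variant_class = c("Missense_Mutation", "Nonsense_Mutation"))
  mm <- binarize_mutations(muts, panel = c("TP53", "ARID1A"),
                           samples = c("S1", "S2"))
  expect_equal(unclass(mm)[, "TP53"], c(S1 = 1L, S2 = 0L))
  expect_equal(unclass(mm)[, "ARID1A"], c(S1 = 0L, S2 = 0L))

  mm2 <- binarize_mutations(muts, c("TP53"), samples = c("S1", "S2", "S3"),
                            sequenced = c("S1", "S2"))
  expect_true(is.na(mm2["S3", "TP53"]))
  expect_identical(attr(mm2, "missing_samples"), "S3")
  expect_error(binarize_mutations(muts, character(0), "S1"), "panel")
})

test_that("enrichment matches the exact Fisher oracle on an extreme table", {
  # gene mutated in all 10 of group A and none of 10 in group B
  samples <- paste0("S", 1:20)
  muts <- tibble::tibble(sample_id = samples[1:10], gene = "G1",
                         variant_class = "Missense_Mutation")
  mm <- binarize_mutations(muts, "G1", samples)
  res <- fisher_enrichment(mm, samples[1:10], samples[11:20])
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$or, (10.5 * 10.5) / (0.5 * 0.5))
  expect_true(res$or_corrected)
  expect_identical(res$test, "fisher")

  # identical frequencies: no enrichment
  muts2 <- tibble::tibble(sample_id = samples[c(1:3, 11:13)], gene = "G1",
                          variant_class = "Missense_Mutation")
  mm2 <- binarize_mutations(muts2, "G1", samples)
  res2 <- fisher_enrichment(mm2, samples[1:10], samples[11:20])
  expect_equal(res2$or, 1)
  expect_equal(res2$p, 1, tolerance = 1e-10)

  expect_error(fisher_enrichment(mm, samples[1:10], samples[10:20]), "disjoint")
})

test_that("enrichment holds its size under a null frequency simulation", {
  set.seed(41)
  hits <- replicate(400, {
    mm <- matrix(rbinom(100, 1, 0.10), ncol = 1,
                 dimnames = list(paste0("S", 1:100), "G"))
    class(mm) <- c("mutation_matrix", class(mm))
    fisher_enrichment(mm, paste0("S", 1:50), paste0("S", 51:100))$p < 0.05
  })
  expect_lte(mean(hits), 0.07)
})

test_that("candidate filtering applies frequency, odds-ratio and p thresholds", {
  set.seed(42)
  n <- 200
  ids <- sprintf("S%03d", 1:n)
  fail <- rep(c(TRUE, FALSE), c(60, 140))
  efs24 <- tibble::tibble(
    sample_id = ids,
    efs24 = factor(ifelse(fail, "fail", "achieve"),
                   levels = c("fail", "achieve", "unevaluable")))
  mm <- cbind(
    enriched = rbinom(n, 1, ifelse(fail, 0.30, 0.08)),   # passes all filters
    rare = c(rbinom(5, 1, 1), rep(0, n - 5)),            # < 5% frequency
    protective = rbinom(n, 1, ifelse(fail, 0.05, 0.25)), # OR < 1
    flat = rbinom(n, 1, 0.15))                           # p too large
  rownames(mm) <- ids
  class(mm) <- c("mutation_matrix", class(mm))
  res <- filter_candidate_genes(mm, efs24, freq_min = 0.05, p_max = 0.15)
  expect_true(res$candidate[res$gene == "enriched"])
  expect_false(res$candidate[res$gene == "rare"])
  expect_false(res$candidate[res$gene == "protective"])
  expect_identical(res$candidate,
                   res$frequency >= 0.05 & res$or > 1 & res$p <= 0.15)

  # invariant to sample order
  perm <- sample(n)
  res_p <- filter_candidate_genes(mm[perm, ], efs24[perm, ],
                                  freq_min = 0.05, p_max = 0.15)
  expect_equal(res, res_p)
})

test_that("an oracle feature is selected by the Lasso with perfect sensitivity", {
  set.seed(43)
  n <- 150
  ids <- sprintf("S%03d", 1:n)
  fail <- rbinom(n, 1, 0.3) == 1
  efs24 <- tibble::tibble(
    sample_id = ids,
    efs24 = factor(ifelse(fail, "fail", "achieve"),
                   levels = c("fail", "achieve", "unevaluable")))
  groups <- tibble::tibble(sample_id = ids, z = rnorm(n),
                           risk = factor(sample(c("low", "intermediate", "high"),
                                                n, replace = TRUE),
                                         levels = c("low", "intermediate", "high")))
  class(groups) <- c("risk_groups", class(groups))
  mm <- cbind(oracle = as.integer(fail), noise = rbinom(n, 1, 0.2))
  rownames(mm) <- ids
  class(mm) <- c("mutation_matrix", class(mm))
  fit <- lasso_integration(groups, mm, efs24, fold_seed = 7)
  expect_true("oracle" %in% fit$selected$feature)
  expect_equal(fit$metrics$sensitivity, 1)
  expect_equal(fit$metrics$specificity, 1)

  all_fail <- efs24; all_fail$efs24[] <- "fail"
  expect_error(lasso_integration(groups, mm, all_fail), "single class")
})

test_that("the union classifier only adds calls, never losing sensitivity", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 80
    ids <- sprintf("S%02d", 1:n)
    groups <- tibble::tibble(
      sample_id = ids, z = rnorm(n),
      risk = factor(sample(c("low", "intermediate", "high"), n, replace = TRUE),
                    levels = c("low", "intermediate", "high")))
    class(groups) <- c("risk_groups", class(groups))
    mm <- cbind(FLAG = rbinom(n, 1, 0.15))
    rownames(mm) <- ids
    class(mm) <- c("mutation_matrix", class(mm))
    efs24 <- tibble::tibble(
      sample_id = ids,
      efs24 = factor(sample(c("fail", "achieve"), n, replace = TRUE),
                     levels = c("fail", "achieve", "unevaluable")))
    ic <- integrated_call(groups, mm, "FLAG", efs24)
    expect_true(all(ic$calls$integrated_high >= ic$calls$expression_high))
    m <- ic$metrics
    expect_gte(m$sensitivity[m$classifier == "integrated"],
               m$sensitivity[m$classifier == "expression_only"])
    expect_lte(m$specificity[m$classifier == "integrated"],
               m$specificity[m$classifier == "expression_only"])
  }
})

test_that("low-risk mutated and high-risk unmutated samples are both called", {
  groups <- tibble::tibble(
    sample_id = c("A", "B", "C"), z = c(2, -2, 0),
    risk = factor(c("high", "low", "intermediate"),
                  levels = c("low", "intermediate", "high")))
  class(groups) <- c("risk_groups", class(groups))
  mm <- cbind(ARID1A = c(0L, 1L, 0L))
  rownames(mm) <- c("A", "B", "C")
  class(mm) <- c("mutation_matrix", class(mm))
  ic <- integrated_call(groups, mm, "ARID1A")
  expect_identical(ic$calls$integrated_high, c(TRUE, TRUE, FALSE))
  expect_error(integrated_call(groups, mm, "TP53"), "flag gene")
})

test_that("pathway burden applies the fold rule with the zero correction", {
  samples <- paste0("S", 1:100)
  grp_a <- samples[1:50]; grp_b <- samples[51:100]
  mk_mm <- function(hits_a, hits_b, gene) {
    muts <- tibble::tibble(sample_id = c(grp_a[seq_len(hits_a)],
                                         grp_b[seq_len(hits_b)]),
                           gene = gene, variant_class = "Missense_Mutation")
    binarize_mutations(muts, gene, samples)
  }
  mm <- cbind(mk_mm(20, 10, "P1G"), mk_mm(12, 10, "P2G"), mk_mm(0, 5, "P3G"))
  class(mm) <- c("mutation_matrix", class(mm))
  sets <- list(strong = "P1G", weak = "P2G", absent_in_a = "P3G",
               off_panel = "ZZZ")
  expect_warning(res <- pathway_mutation_burden(mm, sets, grp_a, grp_b),
                 "off_panel")
  expect_equal(res$fold[res$pathway == "strong"], 2)
  expect_true(res$retained[res$pathway == "strong"])
  expect_equal(res$fold[res$pathway == "weak"], 1.2, tolerance = 1e-12)
  expect_false(res$retained[res$pathway == "weak"])  # below the 1.3-fold rule
  # zero numerator: corrected to half a sample out of 50 => 1% vs 10%
  expect_equal(res$fold[res$pathway == "absent_in_a"], 0.1)
  expect_true(res$retained[res$pathway == "absent_in_a"])
})
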