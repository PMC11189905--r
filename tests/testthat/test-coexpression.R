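test_that("TOM matches the brute-force double-loop formula", {
  for (seed in 1:3) {
    expr <- toy_expr(n_genes = 20 + 5 * seed, n_samples = 15, seed = seed)
    tom <- adjacency_tom(expr, power = 6)
    oracle <- brute_force_tom(unclass(expr), power = 6)
    expect_lt(max(abs(tom - oracle)), 1e-10)
  }
})

test_that("TOM is symmetric, bounded in [0,1], and maximal for a duplicated gene", {
  set.seed(4)
  m <- matrix(rnorm(12 * 20), nrow = 12,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:20)))
  m[2, ] <- m[1, ] * 3 + 1   # perfectly correlated pair
  tom <- adjacency_tom(expression_matrix(m), power = 6)
  expect_equal(max(abs(tom - t(tom))), 0)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 12))
  off <- tom; diag(off) <- NA
  expect_equal(which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1, ] |>
                 unname() |> sort(), c(1, 2))
})

test_that("degenerate network inputs are rejected", {
  expr <- toy_expr(6, 10)
  expect_error(adjacency_tom(expr, power = 0), "power")
  m <- unclass(toy_expr(6, 10))
  m[3, ] <- 5
  expect_error(adjacency_tom(expression_matrix(m), 6), "zero-variance")
  expect_error(pick_soft_threshold(expression_matrix(m)), "zero-variance")
})

test_that("soft-threshold selection warns on pure noise and decreases connectivity", {
  set.seed(10)
  noise <- expression_matrix(matrix(
    rnorm(100 * 50), nrow = 100,
    dimnames = list(paste0("g", 1:100), paste0("s", 1:50))))
  expect_warning(sft <- pick_soft_threshold(noise, powers = 1:6), "argmax")
  expect_true(sft$power %in% 1:6)
  # mean connectivity is monotone decreasing in the power since |cor| <= 1
  expect_true(all(diff(sft$fit_table$mean_k) < 0))
})

test_that("block-structured TOMs yield the planted modules with size filtering", {
  block_tom <- function(sizes, within = 1, between = 0) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    tom <- matrix(between, n, n,
                  dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
    for (k in seq_along(sizes)) tom[lab == k, lab == k] <- within
    diag(tom) <- 1
    tom
  }
  asg <- detect_modules(block_tom(c(30, 30)), min_module_size = 10)
  expect_length(setdiff(unique(asg$module), "grey"), 2L)
  expect_equal(sum(asg$module == "grey"), 0L)

  asg2 <- detect_modules(block_tom(c(30, 5)), min_module_size = 10)
  expect_length(setdiff(unique(asg2$module), "grey"), 1L)
  expect_equal(sum(asg2$module == "grey"), 5L)

  expect_error(detect_modules(block_tom(c(10, 10)), min_module_size = 1),
               "min_module_size")
})

test_that("eigengenes have unit variance, fixed orientation and correct variance explained", {
  # rank-1 module: identical gene vectors
  set.seed(2)
  v <- rnorm(30)
  m <- matrix(rep(v, each = 10), nrow = 10, byrow = FALSE,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  m <- m + 0  # identical rows
  asg <- tibble::tibble(gene_id = rownames(m), module = "m1")
  eig <- module_eigengenes(expression_matrix(m), asg)
  expect_equal(unname(eig$var_explained), 1)
  expect_equal(as.numeric(eig$scores["m1", ]), as.numeric(scale(v)),
               tolerance = 1e-8)

  # two perfectly anti-correlated genes: eigenvalues {2, 0} of the 2x2
  # correlation structure, so the leading component explains everything
  m2 <- rbind(g1 = v, g2 = -v)
  colnames(m2) <- paste0("s", 1:30)
  eig2 <- module_eigengenes(expression_matrix(m2),
                            tibble::tibble(gene_id = c("g1", "g2"), module = "m"))
  expect_equal(unname(eig2$var_explained), 1)
  expect_equal(sd(eig2$scores["m", ]), 1, tolerance = 1e-8)
})

test_that("eigengene equals the SVD leading component and permutes with samples", {
  expr <- toy_expr(20, 50, seed = 6)
  asg <- tibble::tibble(gene_id = rownames(expr), module = "m1")
  eig <- module_eigengenes(expr, asg)
  z <- t(scale(t(unclass(expr))))
  sv <- svd(z)
  expect_equal(abs(cor(eig$scores["m1", ], sv$v[, 1])), 1, tolerance = 1e-8)
  expect_equal(sd(eig$scores["m1", ]), 1, tolerance = 1e-8)

  perm <- sample(ncol(expr))
  eig_p <- module_eigengenes(
    expression_matrix(unclass(expr)[, perm]), asg)
  expect_equal(unname(eig_p$scores["m1", ]), unname(eig$scores["m1", perm]),
               tolerance = 1e-8)

  expect_warning(
    module_eigengenes(expr, tibble::tibble(gene_id = "g1", module = "solo")),
    "single gene")
})

test_that("module-trait correlation recovers exact and missing-trait cases", {
  expr <- toy_expr(10, 40, seed = 3)
  asg <- tibble::tibble(gene_id = rownames(expr), module = "m1")
  eig <- module_eigengenes(expr, asg)
  traits <- tibble::tibble(identical = as.numeric(eig$scores["m1", ]))
  mtc <- module_trait_correlation(eig, traits)
  expect_equal(mtc$r, 1, tolerance = 1e-10)
  expect_lt(mtc$p, 1e-20)
  expect_identical(mtc$stars, "***")

  sparse <- tibble::tibble(mostly_na = c(1, 2, rep(NA, 38)))
  expect_warning(mtc2 <- module_trait_correlation(eig, sparse), "fewer than 3")
  expect_true(is.na(mtc2$r))
})

test_that("risk-module selection maximizes |r| and breaks ties deterministically", {
  mtc <- tibble::tibble(
    module = c("m1", "m2", "m3"), trait = "efs24_fail",
    r = c(0.1, -0.28, 0.05), p = c(0.2, 0.001, 0.5), n = 100, stars = "")
  class(mtc) <- c("module_trait_cor", class(mtc))
  sel <- select_risk_module(mtc, "efs24_fail")
  expect_identical(sel$module, "m2")
  expect_equal(sel$r, -0.28)

  single <- mtc[1, ]
  expect_identical(select_risk_module(single, "efs24_fail")$module, "m1")

  tie <- mtc
  tie$r <- c(0.3, -0.3, 0.1); tie$p <- c(0.01, 0.01, 0.5)
  expect_warning(sel_t <- select_risk_module(tie, "efs24_fail"), "tie")
  expect_identical(sel_t$module, "m1")
})
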