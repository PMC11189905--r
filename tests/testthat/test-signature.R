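test_that("signature assembly intersects contrasts and adds module genes", {
  dge1 <- fake_dge(c("A", "B", "C", "X"), lfc = c(1, 1, -1, 0.5),
                   q = c(0.01, 0.01, 0.01, 0.9))
  dge2 <- fake_dge(c("B", "C", "D", "X"), lfc = c(1, -1, 1, 0.5),
                   q = c(0.01, 0.01, 0.01, 0.9))
  sig <- build_risk_signature(dge1, dge2, module_genes = "E", fdr_threshold = 0.05)
  expect_setequal(sig$gene_id[sig$direction == "up"], "B")
  expect_setequal(sig$gene_id[sig$direction == "down"], c("C", "E"))
  expect_false(any(c("A", "D", "X") %in% sig$gene_id))
  expect_identical(attr(sig, "n_discordant"), 0L |> as.integer())
  expect_identical(sig$provenance[sig$gene_id == "E"], "module")
})

test_that("intersected module genes keep their contrast direction and provenance", {
  dge1 <- fake_dge(c("M", "B"), lfc = c(2, 1), q = c(0.001, 0.001))
  dge2 <- fake_dge(c("M", "B"), lfc = c(1, 1), q = c(0.001, 0.001))
  sig <- build_risk_signature(dge1, dge2, module_genes = c("M", "N"))
  expect_identical(sig$direction[sig$gene_id == "M"], "up")
  expect_identical(sig$provenance[sig$gene_id == "M"], "intersection")
  expect_identical(sig$direction[sig$gene_id == "N"], "down")
})

test_that("discordant genes are excluded and counted; empty signature errors", {
  dge1 <- fake_dge(c("A", "B"), lfc = c(1, 1), q = c(0.01, 0.01))
  dge2 <- fake_dge(c("A", "B"), lfc = c(-1, 1), q = c(0.01, 0.01))
  sig <- build_risk_signature(dge1, dge2, module_genes = character(0))
  expect_false("A" %in% sig$gene_id)
  expect_equal(attr(sig, "n_discordant"), 1L)

  empty1 <- fake_dge("A", 1, 0.9)
  expect_error(build_risk_signature(empty1, empty1, character(0)),
               "empty signature")
})

test_that("totalscore matches the rank-normalization formula on hand cases", {
  x <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4, g5 = 5)
  expr <- expression_matrix(cbind(sA = x, sB = x))
  mk_sig <- function(up = character(0), down = character(0)) {
    s <- tibble::tibble(gene_id = c(up, down),
                        direction = c(rep("up", length(up)), rep("down", length(down))),
                        provenance = "intersection")
    class(s) <- c("gene_signature", class(s)); s
  }
  # the two most-expressed genes as the up set: maximal one-direction score
  expect_equal(total_score(expr, mk_sig(up = c("g4", "g5")))$totalscore[1], 0.5)
  # the two least-expressed genes as the up set: minimal
  expect_equal(total_score(expr, mk_sig(up = c("g1", "g2")))$totalscore[1], -0.5)
  # symmetric ranks {1, 5}: midpoint, score zero
  expect_equal(total_score(expr, mk_sig(up = c("g1", "g5")))$totalscore[1], 0)
  # bidirectional extreme: up on top, down at bottom reaches +1
  expect_equal(total_score(expr, mk_sig(up = c("g4", "g5"),
                                        down = c("g1", "g2")))$totalscore[1], 1)
})

test_that("totalscore equals the brute-force oracle over random sets", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- rnorm(n)
    names(x) <- paste0("g", 1:n)
    up <- sample(names(x), sample(0:2, 1))
    down <- sample(setdiff(names(x), up), sample(1:2, 1))
    expr <- expression_matrix(cbind(s1 = x, s2 = rev(x) + 0))
    rownames(expr) <- names(x)
    sig <- tibble::tibble(
      gene_id = c(up, down),
      direction = c(rep("up", length(up)), rep("down", length(down))),
      provenance = "intersection")
    got <- total_score(expr, sig)$totalscore[1]
    want <- brute_force_totalscore(x, match(up, names(x)), match(down, names(x)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("totalscore is rank-based and direction-antisymmetric", {
  expr <- toy_expr(30, 10, seed = 12)
  genes <- rownames(expr)
  sig <- tibble::tibble(gene_id = genes[1:8],
                        direction = rep(c("up", "down"), each = 4),
                        provenance = "intersection")
  s1 <- total_score(expr, sig)
  s2 <- total_score(expression_matrix(exp(unclass(expr))), sig)
  expect_equal(s1$totalscore, s2$totalscore, tolerance = 1e-12)

  flipped <- sig
  flipped$direction <- ifelse(sig$direction == "up", "down", "up")
  s3 <- total_score(expr, flipped)
  expect_equal(s3$totalscore, -s1$totalscore, tolerance = 1e-12)
})

test_that("missing signature genes are dropped with a coverage report", {
  expr <- toy_expr(10, 5)
  sig <- tibble::tibble(gene_id = c("g1", "g2", "nope1", "nope2"),
                        direction = c("up", "down", "up", "down"),
                        provenance = "intersection")
  sc <- total_score(expr, sig)
  expect_equal(attr(sc, "coverage"), 0.5)
  sig_none <- tibble::tibble(gene_id = "absent", direction = "up",
                             provenance = "module")
  expect_error(total_score(expr, sig_none), "no signature genes")
})

test_that("failure-prone samples score higher on the planted signature", {
  higher <- vapply(1:5, function(s) {
    co <- simulate_cohort(simulation_design(
      n_nd = 150L, n_rr = 0L, n_genes = 400L, module_sizes = c(60L, 40L),
      risk_module_index = 2L, seed = s))
    genes <- truth_genes(co)
    sig <- tibble::tibble(gene_id = genes$gene_id[genes$is_risk_module],
                          direction = "down", provenance = "module")
    sc <- total_score(co$expression, sig)
    tr <- co$truth$samples
    mean(sc$totalscore[tr$efs24_fail]) > mean(sc$totalscore[!tr$efs24_fail])
  }, logical(1))
  expect_true(all(higher))
})

test_that("stratification cuts at +/- sd with boundaries intermediate", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"), totalscore = c(-2, 0, 2),
                       z = c(-2, 0, 2))
  g <- stratify(sc, sd_cut = 1)
  expect_identical(as.character(g$risk), c("low", "intermediate", "high"))

  sc2 <- tibble::tibble(sample_id = c("a", "b", "c"), totalscore = c(1, 0, 2),
                        z = c(1, 0, 2))
  g2 <- stratify(sc2, sd_cut = 1)
  expect_identical(as.character(g2$risk[1]), "intermediate")

  flat <- tibble::tibble(sample_id = letters[1:4], totalscore = rep(1, 4))
  expect_error(stratify(flat), "zero variance")
})

test_that("module direction can follow a positively correlated module", {
  dge1 <- fake_dge("A", 1, 0.01)
  dge2 <- fake_dge("A", 1, 0.01)
  sig <- build_risk_signature(dge1, dge2, module_genes = c("M"),
                              module_direction = "up")
  expect_identical(sig$direction[sig$gene_id == "M"], "up")
})
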