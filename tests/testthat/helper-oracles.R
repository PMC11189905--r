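# Independent oracles and small fixture builders shared across tests.

# Brute-force topological overlap: direct double-loop evaluation of
# TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
brute_force_tom <- function(expr, power) {
  a <- abs(cor(t(expr)))^power
  diag(a) <- 1
  g <- nrow(a)
  k <- sapply(seq_len(g), function(i) sum(a[i, -i]))
  tom <- matrix(0, g, g)
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# Brute-force bidirectional rank score for a single sample, written from the
# normalization definition (independent of the package implementation).
brute_force_totalscore <- function(x, up, down) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  one_dir <- function(ranks, idx) {
    s <- length(idx)
    if (s == 0) return(0)
    mr <- mean(ranks[idx])
    minp <- (s + 1) / 2
    maxp <- (2 * n - s + 1) / 2
    (mr - minp) / (maxp - minp) - 0.5
  }
  one_dir(r, up) + one_dir(n + 1 - r, down)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# small expression matrix with named genes/samples
toy_expr <- function(n_genes = 10, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  expression_matrix(m)
}

# minimal dge_result tibble for signature-assembly tests
fake_dge <- function(genes, lfc, q) {
  out <- tibble::tibble(gene_id = genes, log2fc = lfc, t = lfc, p = q, q = q,
                        zero_variance = FALSE)
  class(out) <- c("dge_result", class(out))
  out
}

# small clinical tibble
toy_clinical <- function(n = 6, cohort = "nd") {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    efs_time = seq(10, 10 + 5 * (n - 1), by = 5), efs_event = rep(c(TRUE, FALSE), length.out = n),
    os_time = seq(20, 20 + 5 * (n - 1), by = 5), os_event = rep(FALSE, n),
    ipi = rep(2L, n), coo = rep("GCB", n), cohort = rep(cohort, n))
}

# adjusted Rand index between two labelings (closed-form from the pair
# contingency table); cross-checked against mclust in the tests
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
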