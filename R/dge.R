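# Differential expression (moderated t on log expression), FDR adjustment,
# and hypergeometric overrepresentation.

#' Differential expression between two sample groups
#'
#' Per gene: the difference of group means on the log scale (reported as
#' `log2fc`, group2 minus group1), a two-sample t-statistic with an
#' empirical-Bayes shrunken variance (each gene's pooled variance shrunk
#' toward the grand mean variance across genes with `d0` prior
#' pseudo-degrees-of-freedom), a two-sided p-value from the t distribution
#' with residual-plus-prior degrees of freedom, and Benjamini-Hochberg
#' adjusted q-values. Genes with any missing value in either group are
#' dropped for the contrast; genes with zero pooled variance get `p = 1`
#' and are flagged.
#'
#' @param expr Expression matrix (genes x samples).
#' @param group1,group2 Disjoint character vectors of sample identifiers,
#'   each of size >= 3.
#' @param d0 Prior degrees of freedom of the variance shrinkage (default 4;
#'   0 recovers the ordinary two-sample t-test).
#' @return A tibble of class `dge_result`: `gene_id`, `log2fc`, `t`, `p`,
#'   `q`, `zero_variance`.
#' @export
differential_expression <- function(expr, group1, group2, d0 = 4) {
  x <- unclass(expr)
  if (length(intersect(group1, group2)) > 0L) abort("groups must be disjoint")
  if (length(group1) < 3L || length(group2) < 3L) abort("each group needs at least 3 samples")
  miss <- setdiff(c(group1, group2), colnames(x))
  if (length(miss) > 0L) abort(sprintf("sample(s) absent from expression matrix: %s",
                                       paste(head(miss, 3L), collapse = ", ")))
  x1 <- x[, group1, drop = FALSE]
  x2 <- x[, group2, drop = FALSE]
  complete <- rowSums(is.na(x1)) == 0L & rowSums(is.na(x2)) == 0L
  x1 <- x1[complete, , drop = FALSE]; x2 <- x2[complete, , drop = FALSE]
  n1 <- length(group1); n2 <- length(group2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
  df_res <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_res
  s2_prior <- mean(s2)
  s2_post <- (d0 * s2_prior + df_res * s2) / (d0 + df_res)
  lfc <- m2 - m1
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  zerovar <- s2 == 0 & s2_post == 0
  tt <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pt(-abs(tt), df = df_res + d0)
  p[zerovar] <- 1
  out <- tibble::tibble(gene_id = rownames(x1), log2fc = unname(lfc),
                        t = unname(tt), p = unname(p), q = bh_adjust(unname(p)),
                        zero_variance = unname(zerovar))
  class(out) <- c("dge_result", class(out))
  attr(out, "groups") <- list(group1 = group1, group2 = group2)
  attr(out, "d0") <- d0
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with the usual monotonicity
#' enforcement, returned in the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must be in [0, 1] with no missing values")
  }
  p.adjust(pvals, method = "BH")
}

#' Hypergeometric overrepresentation of gene sets in a query list
#'
#' Upper-tail hypergeometric test per set: with universe size `N`, set size
#' `K` (after intersecting each set with the universe), query size `n` and
#' hit count `k`, the p-value is `P(X >= k)`. The enrichment ratio is
#' `(k/n) / (K/N)` and q-values are Benjamini-Hochberg across sets.
#'
#' @param query Character vector of genes (must be a subset of `universe`).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all testable genes.
#' @return A tibble of class `ora_result`: `set`, `hits`, `set_size`,
#'   `query_size`, `universe_size`, `enrichment`, `p`, `q`.
#' @export
overrepresentation <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) abort("query genes must be contained in the universe")
  N <- length(universe); n <- length(query)
  res <- purrr::imap_dfr(sets, function(genes, set) {
    genes <- intersect(genes, universe)
    K <- length(genes)
    k <- length(intersect(genes, query))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    enr <- if (K > 0L && n > 0L) (k / n) / (K / N) else NA_real_
    tibble::tibble(set = set, hits = k, set_size = K, query_size = n,
                   universe_size = N, enrichment = enr, p = p)
  })
  res$q <- bh_adjust(res$p)
  class(res) <- c("ora_result", class(res))
  res
}
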