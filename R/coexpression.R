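# Weighted co-expression network: soft threshold, topological overlap,
# module detection, eigengenes, module-trait correlation.

module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue")

check_no_constant_genes <- function(expr) {
  v <- apply(unclass(expr), 1L, var)
  if (any(v == 0 | !is.finite(v))) {
    abort(sprintf(
      "zero-variance gene(s) present (e.g. '%s'); filter constant genes before network construction",
      rownames(expr)[which(v == 0 | !is.finite(v))[1L]]))
  }
  invisible(expr)
}

#' Choose a soft-threshold power for network construction
#'
#' For each candidate power the unsigned adjacency `|cor|^power` is formed
#' and the scale-free topology fit is measured: node connectivities are
#' binned (10 bins), and the signed R-squared of the regression of
#' log10 p(k) on log10 k is recorded together with the mean connectivity.
#' The chosen power is the smallest reaching fit R-squared >= `rsq_target`;
#' if no power reaches the target the grid argmax is returned with a
#' warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param powers Integer grid of candidate powers (>= 1).
#' @param rsq_target Scale-free fit target (default 0.8).
#' @param n_bins Connectivity histogram bins for the fit.
#' @return A list of class `soft_threshold`: `power` (chosen), and
#'   `fit_table`, a tibble with columns `power`, `r_squared` (signed),
#'   `slope`, `mean_k`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12L, 14L, 16L),
                                rsq_target = 0.8, n_bins = 10L) {
  check_no_constant_genes(expr)
  if (any(powers < 1)) abort("powers must be >= 1")
  ac <- abs(cor(t(unclass(expr))))
  fit <- purrr::map_dfr(sort(unique(powers)), function(p) {
    a <- ac^p
    k <- rowSums(a) - 1  # exclude self-adjacency
    sf <- scale_free_fit(k, n_bins)
    tibble::tibble(power = p, r_squared = sf$r_squared, slope = sf$slope,
                   mean_k = mean(k))
  })
  ok <- which(fit$r_squared >= rsq_target)
  if (length(ok) > 0L) {
    power <- fit$power[ok[1L]]
  } else {
    power <- fit$power[which.max(fit$r_squared)]
    warn(sprintf(
      "no power reached scale-free fit R^2 >= %.2f; using grid argmax (power %d, R^2 = %.2f)",
      rsq_target, power, max(fit$r_squared)))
  }
  structure(list(power = as.integer(power), fit_table = fit),
            class = "soft_threshold")
}

# signed scale-free fit R^2 from a connectivity vector
scale_free_fit <- function(k, n_bins = 10L) {
  brks <- seq(min(k), max(k), length.out = n_bins + 1L)
  if (length(unique(brks)) < 2L) return(list(r_squared = 0, slope = 0))
  bin <- cut(k, breaks = brks, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0 & km > 0
  if (sum(keep) < 3L) return(list(r_squared = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(km[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2L])
  list(r_squared = -sign(slope) * r2, slope = slope)
}

#' Adjacency and topological overlap matrix
#'
#' Unsigned soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^power` with
#' unit diagonal, augmented to the topological overlap similarity
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' the shared-neighbor sum runs over `u != i, j` and
#' `k_i = sum_{u != i} a_iu`. The result is symmetric with entries in
#' `[0, 1]` and unit diagonal.
#'
#' @param expr Expression matrix (genes x samples).
#' @param power Soft-threshold power (integer >= 1).
#' @return Symmetric TOM similarity matrix (genes x genes).
#' @export
adjacency_tom <- function(expr, power) {
  assert_scalar_number(power, "power", lower = 1)
  check_no_constant_genes(expr)
  a <- abs(cor(t(unclass(expr))))^power
  diag(a) <- 1
  k <- rowSums(a) - 1
  num <- a %*% a - 2 * a + a   # sum_{u != i,j} a_iu a_uj + a_ij
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2    # remove floating-point asymmetry
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed fraction (`cut_quantile`) of the dendrogram height, in the
#' spirit of dynamic branch cutting. Clusters smaller than
#' `min_module_size` are relegated to the unassigned (`"grey"`) label. When
#' the expression matrix is supplied, modules whose eigengenes correlate
#' above `merge_cor` are merged iteratively. Modules are named by color in
#' decreasing size order, following network-analysis convention.
#'
#' @param tom Square symmetric TOM similarity matrix with gene dimnames.
#' @param min_module_size Smallest cluster kept as a module (>= 2).
#' @param expr Optional expression matrix enabling the eigengene merge step.
#' @param merge_cor Eigengene correlation above which modules merge.
#' @param cut_quantile Fraction of the maximum merge height at which the
#'   tree is cut.
#' @return A tibble of class `module_assignment` with columns `gene_id` and
#'   `module` (`"grey"` = unassigned); the dendrogram and cut height are
#'   kept as attributes.
#' @export
detect_modules <- function(tom, min_module_size = 30L, expr = NULL,
                           merge_cor = 0.75, cut_quantile = 0.99) {
  if (min_module_size < 2) abort("min_module_size must be at least 2")
  if (!isTRUE(all.equal(tom, t(tom), tolerance = 1e-8))) {
    abort("TOM must be symmetric")
  }
  genes <- rownames(tom) %theni% paste0("g", seq_len(nrow(tom)))
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  cut_h <- cut_quantile * max(tree$height)
  raw <- cutree(tree, h = cut_h)

  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- ifelse(raw %in% as.integer(keep), as.character(raw), "grey")

  if (!is.null(expr) && length(setdiff(unique(lab), "grey")) > 1L) {
    lab <- merge_close_modules(lab, genes, expr, merge_cor)
  }

  # order modules by size, name by the conventional color palette
  mods <- setdiff(names(sort(table(lab[lab != "grey"]), decreasing = TRUE)), "grey")
  new_names <- c(module_palette, sprintf("module%02d", seq_len(max(0L, length(mods) - length(module_palette)))))
  map <- setNames(new_names[seq_along(mods)], mods)
  lab <- ifelse(lab == "grey", "grey", unname(map[lab]))

  out <- tibble::tibble(gene_id = genes, module = lab)
  class(out) <- c("module_assignment", class(out))
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- cut_h
  out
}

merge_close_modules <- function(lab, genes, expr, merge_cor) {
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2L) break
    asg <- tibble::tibble(gene_id = genes, module = lab)
    eig <- module_eigengenes(expr, asg, quiet = TRUE)
    cc <- cor(t(eig$scores))
    diag(cc) <- 0
    mx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[mx[1L], mx[2L]] <= merge_cor) break
    from <- rownames(cc)[mx[1L]]; to <- rownames(cc)[mx[2L]]
    lab[lab == from] <- to
  }
  lab
}

#' Module eigengenes
#'
#' For each module, the first principal component of the gene-standardized
#' submatrix across samples: each eigengene is scaled to unit sample
#' variance and sign-oriented so that its correlation with the module's
#' mean standardized expression is non-negative. The fraction of module
#' variance explained by the eigengene is reported.
#'
#' @param expr Expression matrix (genes x samples).
#' @param modules A [detect_modules()] assignment (tibble with `gene_id`,
#'   `module`); the `"grey"` unassigned label is skipped.
#' @param quiet Suppress the single-gene-module warning.
#' @return A list of class `eigengene_matrix`: `scores` (modules x samples
#'   matrix, unit variance rows) and `var_explained` (named vector).
#' @export
module_eigengenes <- function(expr, modules, quiet = FALSE) {
  x <- unclass(expr)
  mods <- setdiff(unique(modules$module), "grey")
  if (length(mods) == 0L) abort("no modules to summarize")
  missing_genes <- setdiff(modules$gene_id, rownames(x))
  if (length(missing_genes) > 0L) {
    abort(sprintf("module genes absent from expression matrix (e.g. '%s')", missing_genes[1L]))
  }
  scores <- matrix(NA_real_, nrow = length(mods), ncol = ncol(x),
                   dimnames = list(mods, colnames(x)))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    g <- modules$gene_id[modules$module == m]
    sub <- x[g, , drop = FALSE]
    if (length(g) == 1L) {
      if (!quiet) warn(sprintf("module '%s' has a single gene; eigengene is that gene standardized", m))
      e <- as.numeric(scale(sub[1L, ]))
      ve[m] <- 1
    } else {
      z <- t(scale(t(sub)))  # standardize each gene across samples
      sv <- svd(z, nu = 0, nv = 1)
      e <- sv$v[, 1L]
      e <- e / sd(e)
      # orient to the module mean; when the standardized mean is constant
      # (perfectly anti-correlated pair) the orientation is left as computed
      zm <- colMeans(z)
      if (sd(zm) > 0 && cor(e, zm) < 0) e <- -e
      ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    }
    scores[m, ] <- e
  }
  structure(list(scores = scores, var_explained = ve),
            class = "eigengene_matrix")
}

#' @export
tidy.eigengene_matrix <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id", values_to = "score")
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each trait over samples with
#' a non-missing trait value, with two-sided t-distribution p-values and
#' star annotations at 0.05 / 0.001 / 0.0001. Binary traits should be coded
#' 0/1 (e.g. failure of the 24-month event-free endpoint = 1).
#'
#' @param eig An [module_eigengenes()] result.
#' @param traits Data frame of per-sample numeric traits, rows aligned to
#'   the eigengene samples (a `sample_id` column, if present, is used to
#'   align explicitly).
#' @return A tibble of class `module_trait_cor`: `module`, `trait`, `r`,
#'   `p`, `n`, `stars`.
#' @export
module_trait_correlation <- function(eig, traits) {
  traits <- tibble::as_tibble(traits)
  samples <- colnames(eig$scores)
  if ("sample_id" %in% colnames(traits)) {
    idx <- match(samples, traits$sample_id)
    if (anyNA(idx)) abort("traits missing rows for some eigengene samples")
    traits <- traits[idx, setdiff(colnames(traits), "sample_id"), drop = FALSE]
  } else if (nrow(traits) != length(samples)) {
    abort("traits must have one row per sample")
  }
  out <- tidyr::expand_grid(module = rownames(eig$scores), trait = colnames(traits))
  res <- purrr::pmap_dfr(out, function(module, trait) {
    e <- eig$scores[module, ]
    tvec <- as.numeric(traits[[trait]])
    keep <- !is.na(tvec)
    n <- sum(keep)
    if (n < 3L || sd(tvec[keep]) == 0) {
      warn(sprintf("trait '%s' has fewer than 3 informative values; correlation set missing", trait))
      return(tibble::tibble(module = module, trait = trait,
                            r = NA_real_, p = NA_real_, n = n))
    }
    r <- cor(e[keep], tvec[keep])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    tibble::tibble(module = module, trait = trait, r = r, p = max(p, .Machine$double.xmin), n = n)
  })
  res$stars <- dplyr::case_when(
    is.na(res$p) ~ "",
    res$p < 1e-4 ~ "***",
    res$p < 1e-3 ~ "**",
    res$p < 0.05 ~ "*",
    TRUE ~ "")
  class(res) <- c("module_trait_cor", class(res))
  res
}

#' Select the module most correlated with a trait
#'
#' Returns the module with the largest absolute Pearson correlation with
#' the named trait. Ties in |r| beyond 1e-12 break by smaller p, then by
#' lexicographic module label, with a warning.
#'
#' @param mtc A [module_trait_correlation()] result.
#' @param trait Trait name.
#' @param modules Optional [detect_modules()] assignment; when supplied the
#'   member genes of the selected module are returned too.
#' @return A list of class `risk_module`: `module`, `r`, `p`, `genes`.
#' @export
select_risk_module <- function(mtc, trait, modules = NULL) {
  cand <- dplyr::filter(mtc, .data$trait == !!trait, !is.na(.data$r))
  if (nrow(cand) == 0L) abort(sprintf("trait '%s' not present in correlation table", trait))
  best_abs <- max(abs(cand$r))
  tied <- cand[abs(abs(cand$r) - best_abs) <= 1e-12, , drop = FALSE]
  if (nrow(tied) > 1L) {
    tied <- tied[order(tied$p, tied$module), , drop = FALSE]
    warn(sprintf("tie in |r| among modules %s; choosing '%s'",
                 paste(tied$module, collapse = ", "), tied$module[1L]))
  }
  sel <- tied[1L, ]
  genes <- if (!is.null(modules)) modules$gene_id[modules$module == sel$module] else character(0)
  structure(list(module = sel$module, r = sel$r, p = sel$p, genes = genes),
            class = "risk_module")
}
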