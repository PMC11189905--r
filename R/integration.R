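# Mutation-side analyses: binarization, enrichment, candidate filtering,
# Lasso integration, union classifier, pathway mutation burden.

#' Binarize a mutation record table over a gene panel
#'
#' One row per sample, one column per panel gene, 1 = any qualifying
#' variant. Samples absent from the record table get all-zero rows when
#' listed as sequenced; samples not sequenced get `NA` rows and are flagged
#' in the `"missing_samples"` attribute (and excluded from frequency
#' computations downstream).
#'
#' @param muts Mutation tibble (`sample_id`, `gene`, `variant_class`).
#' @param panel Character vector of panel genes.
#' @param samples Character vector of samples to represent as rows.
#' @param sequenced Samples actually assayed (default: all of `samples`).
#' @return A samples x genes 0/1 matrix of class `mutation_matrix`.
#' @export
binarize_mutations <- function(muts, panel, samples, sequenced = samples) {
  if (length(panel) == 0L) abort("panel must be non-empty")
  mm <- matrix(0L, nrow = length(samples), ncol = length(panel),
               dimnames = list(samples, panel))
  hit <- muts[muts$sample_id %in% samples & muts$gene %in% panel, , drop = FALSE]
  if (nrow(hit) > 0L) mm[cbind(hit$sample_id, hit$gene)] <- 1L
  missing <- setdiff(samples, sequenced)
  if (length(missing) > 0L) mm[missing, ] <- NA_integer_
  class(mm) <- c("mutation_matrix", class(mm))
  attr(mm, "missing_samples") <- missing
  mm
}

haldane_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    list(or = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)), corrected = TRUE)
  } else {
    list(or = (a * d) / (b * c), corrected = FALSE)
  }
}

#' Per-gene mutation enrichment between two sample groups
#'
#' For each gene a 2x2 table (mutated/wild-type by group) is tested with
#' Fisher's exact test when any expected cell count is below 5 and a
#' chi-square test otherwise. Odds ratios are the cross-product, with a
#' Haldane 0.5 correction (flagged) when a zero cell occurs; q-values are
#' Benjamini-Hochberg across genes.
#'
#' @param mm A [binarize_mutations()] matrix.
#' @param group_a,group_b Disjoint sample identifier vectors (each >= 2).
#' @return A tibble of class `enrichment_result`: `gene`, `freq_a`,
#'   `freq_b`, `or`, `or_corrected`, `test`, `p`, `q`.
#' @export
fisher_enrichment <- function(mm, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0L) abort("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) abort("each group needs at least 2 samples")
  res <- purrr::map_dfr(colnames(mm), function(g) {
    xa <- mm[intersect(group_a, rownames(mm)), g]
    xb <- mm[intersect(group_b, rownames(mm)), g]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    tab <- matrix(c(sum(xa == 1L), sum(xa == 0L), sum(xb == 1L), sum(xb == 0L)), nrow = 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expected < 5) || any(tab == 0)
    p <- if (use_fisher) fisher.test(tab)$p.value else
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    orr <- haldane_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    tibble::tibble(gene = g, freq_a = mean(xa), freq_b = mean(xb),
                   or = orr$or, or_corrected = orr$corrected,
                   test = if (use_fisher) "fisher" else "chisq", p = p)
  })
  res$q <- bh_adjust(res$p)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Filter candidate mutation genes for outcome integration
#'
#' Retains genes with mutation frequency at least `freq_min` among
#' evaluable samples, odds ratio above 1 for failure versus achieve of the
#' 24-month event-free endpoint (Haldane-corrected on zero cells), and
#' chi-square `P <= p_max` for association with that endpoint.
#'
#' @param mm A [binarize_mutations()] matrix.
#' @param efs24 A [derive_efs24()] status tibble; unevaluable samples are
#'   excluded.
#' @param freq_min Minimum frequency (default 0.05).
#' @param p_max Maximum chi-square p (default 0.15).
#' @return A tibble with per-gene `frequency`, `or`, `p` and a `candidate`
#'   flag, sorted by p.
#' @export
filter_candidate_genes <- function(mm, efs24, freq_min = 0.05, p_max = 0.15) {
  ev <- efs24[efs24$efs24 %in% c("fail", "achieve"), , drop = FALSE]
  ids <- intersect(ev$sample_id, rownames(mm))
  ids <- ids[stats::complete.cases(mm[ids, , drop = FALSE])]
  if (length(ids) < 20L) abort("need at least 20 evaluable sequenced samples")
  fail <- ids[ev$efs24[match(ids, ev$sample_id)] == "fail"]
  achv <- setdiff(ids, fail)
  res <- purrr::map_dfr(sort(colnames(mm)), function(g) {
    xf <- mm[fail, g]; xa <- mm[achv, g]
    tab <- matrix(c(sum(xf == 1L), sum(xf == 0L), sum(xa == 1L), sum(xa == 0L)), nrow = 2)
    orr <- haldane_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    if (!is.finite(p)) p <- 1
    tibble::tibble(gene = g, frequency = mean(mm[ids, g]), or = orr$or, p = p)
  })
  res$candidate <- res$frequency >= freq_min & res$or > 1 & res$p <= p_max
  dplyr::arrange(res, .data$p)
}

#' L1-penalized integration of mutations with the expression risk strata
#'
#' Logistic Lasso of 24-month failure on the risk-stratum indicators
#' (intermediate and high, low as reference) plus candidate mutation
#' indicators. The penalty is chosen by 10-fold
#' cross-validated deviance with outcome-stratified, seeded folds, at the
#' one-standard-error rule by default (parsimonious selection). Nonzero
#' coefficients identify the retained features; classifier metrics of the
#' fitted model thresholded at probability 0.5 are reported.
#'
#' @param risk A [stratify()] result.
#' @param mm A [binarize_mutations()] matrix restricted (or restrictable
#'   via `candidates`) to candidate genes.
#' @param efs24 A [derive_efs24()] status tibble.
#' @param candidates Optional character vector selecting mutation columns.
#' @param fold_seed Seed for the cross-validation folds.
#' @param lambda_rule `"lambda.1se"` (default; largest penalty within one
#'   standard error of the CV-deviance minimum, the conventional parsimony
#'   rule) or `"lambda.min"`.
#' @return A list of class `lasso_integration`: `selected` (tibble feature,
#'   coefficient), `metrics`, `lambda`, `fold_seed`, `fit`.
#' @export
lasso_integration <- function(risk, mm, efs24, candidates = NULL,
                              fold_seed = 1L,
                              lambda_rule = c("lambda.1se", "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  if (!is.null(candidates)) mm <- mm[, intersect(candidates, colnames(mm)), drop = FALSE]
  ev <- efs24[efs24$efs24 %in% c("fail", "achieve"), , drop = FALSE]
  ids <- Reduce(intersect, list(ev$sample_id, risk$sample_id, rownames(mm)))
  ids <- ids[stats::complete.cases(mm[ids, , drop = FALSE])]
  y <- as.integer(ev$efs24[match(ids, ev$sample_id)] == "fail")
  if (length(unique(y)) < 2L) abort("outcome has a single class; cannot fit")
  r <- risk$risk[match(ids, risk$sample_id)]
  x <- cbind(risk_intermediate = as.integer(r == "intermediate"),
             risk_high = as.integer(r == "high"),
             mm[ids, , drop = FALSE])
  foldid <- with_substream(fold_seed, "cv_folds", {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(10L), length(idx)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance")
  cf <- coef(cv, s = lambda_rule)
  nz <- which(as.numeric(cf)[-1L] != 0)
  selected <- tibble::tibble(feature = rownames(cf)[-1L][nz],
                             coefficient = as.numeric(cf)[-1L][nz])
  prob <- as.numeric(predict(cv, newx = x, s = lambda_rule, type = "response"))
  metrics <- classifier_metrics(prob > 0.5, y == 1L)
  structure(list(selected = selected, metrics = metrics,
                 lambda = cv[[lambda_rule]], lambda_rule = lambda_rule,
                 fold_seed = fold_seed,
                 samples = ids, fit = cv),
            class = "lasso_integration")
}

#' @export
tidy.lasso_integration <- function(x, ...) x$selected

#' @export
glance.lasso_integration <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(lambda = x$lambda), x$metrics)
}

#' Union classifier: high-risk expression label OR flagged-gene mutation
#'
#' Calls a sample integrated-high when its expression risk stratum is high
#' or it carries a mutation in the flag gene; by construction this can only
#' add calls, so sensitivity never drops (and specificity never rises)
#' relative to the expression label alone. Metrics against 24-month
#' failure, including the failure capture fraction, are reported for both
#' the expression-only and integrated classifiers.
#'
#' @param risk A [stratify()] result.
#' @param mm A [binarize_mutations()] matrix containing `flag_gene`.
#' @param flag_gene Gene whose mutation joins the high-risk call.
#' @param efs24 Optional [derive_efs24()] tibble for metrics.
#' @return A list of class `integrated_call`: `calls` (tibble sample_id,
#'   expression_high, mutated, integrated_high), `metrics` (tibble with
#'   rows expression_only and integrated, when `efs24` is given),
#'   `flag_gene`.
#' @export
integrated_call <- function(risk, mm, flag_gene, efs24 = NULL) {
  if (!flag_gene %in% colnames(mm)) abort(sprintf("flag gene '%s' not in mutation matrix", flag_gene))
  ids <- intersect(risk$sample_id, rownames(mm))
  expr_high <- unname(risk$risk[match(ids, risk$sample_id)] == "high")
  mut <- unname(mm[ids, flag_gene] == 1L)
  mut[is.na(mut)] <- FALSE
  calls <- tibble::tibble(sample_id = ids, expression_high = expr_high,
                          mutated = mut, integrated_high = expr_high | mut)
  metrics <- NULL
  if (!is.null(efs24)) {
    ev <- efs24[efs24$efs24 %in% c("fail", "achieve"), , drop = FALSE]
    sub <- calls[calls$sample_id %in% ev$sample_id, , drop = FALSE]
    truth <- ev$efs24[match(sub$sample_id, ev$sample_id)] == "fail"
    metrics <- dplyr::bind_rows(
      dplyr::mutate(classifier_metrics(sub$expression_high, truth),
                    classifier = "expression_only", .before = 1L),
      dplyr::mutate(classifier_metrics(sub$integrated_high, truth),
                    classifier = "integrated", .before = 1L))
  }
  structure(list(calls = calls, metrics = metrics, flag_gene = flag_gene),
            class = "integrated_call")
}

#' Pathway mutation burden between two groups
#'
#' Per pathway, the percentage of samples in each group carrying a
#' mutation in at least one member gene; pathways changing by at least
#' `fold_min`-fold in either direction are retained. A zero numerator is
#' replaced by half a sample (Haldane-style) before forming the fold.
#' Pathways with no panel genes are skipped with a warning.
#'
#' @param mm A [binarize_mutations()] matrix.
#' @param sets Named list of pathway gene sets.
#' @param group_a,group_b Disjoint sample identifier vectors.
#' @param fold_min Retention fold threshold (default 1.3).
#' @return A tibble: `pathway`, `pct_a`, `pct_b`, `fold`, `retained`.
#' @export
pathway_mutation_burden <- function(mm, sets, group_a, group_b, fold_min = 1.3) {
  if (length(intersect(group_a, group_b)) > 0L) abort("groups must be disjoint")
  pct_mutated <- function(ids, genes) {
    sub <- mm[intersect(ids, rownames(mm)), genes, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    c(n = nrow(sub), hits = sum(rowSums(sub) > 0))
  }
  purrr::imap_dfr(sets, function(genes, pw) {
    genes <- intersect(genes, colnames(mm))
    if (length(genes) == 0L) {
      warn(sprintf("pathway '%s' has no genes on the panel; skipped", pw))
      return(NULL)
    }
    a <- pct_mutated(group_a, genes); b <- pct_mutated(group_b, genes)
    pa <- 100 * a[["hits"]] / a[["n"]]; pb <- 100 * b[["hits"]] / b[["n"]]
    fa <- if (a[["hits"]] == 0L) 100 * 0.5 / a[["n"]] else pa
    fb <- if (b[["hits"]] == 0L) 100 * 0.5 / b[["n"]] else pb
    fold <- fa / fb
    tibble::tibble(pathway = pw, pct_a = pa, pct_b = pb, fold = fold,
                   retained = fold >= fold_min | fold <= 1 / fold_min)
  })
}
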