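# Directional risk-signature assembly, rank-based bidirectional scoring,
# and SD-based stratification.

#' Assemble a directional risk signature from two contrasts and a module
#'
#' Genes significant (q below `fdr_threshold`) in both contrasts with
#' concordant fold-change sign are intersected; their direction comes from
#' the first (failure vs achieve) contrast. The co-expression risk-module
#' genes are then added: module genes not already intersected are assigned
#' direction `"down"` (the module is negatively correlated with failure,
#' so its genes are lower in failing cases), while module genes that also
#' intersected keep their contrast-derived direction and `"intersection"`
#' provenance. Significant-in-both genes with discordant signs are excluded
#' and counted.
#'
#' @param dge_fail [differential_expression()] result for failures vs
#'   achievers (log2fc positive = higher in failures).
#' @param dge_rr [differential_expression()] result for the second contrast
#'   (relapsed/refractory vs achievers, same orientation).
#' @param module_genes Character vector of risk-module genes.
#' @param fdr_threshold FDR cutoff applied to both contrasts.
#' @param module_direction Direction assigned to module genes without
#'   differential-expression evidence: `"down"` (default, for a module
#'   negatively correlated with failure) or `"up"` (for a positively
#'   correlated module).
#' @return A tibble of class `gene_signature`: `gene_id`, `direction`
#'   (`"up"`/`"down"`), `provenance` (`"intersection"`/`"module"`); the
#'   number of discordant genes and the threshold are kept as attributes.
#' @export
build_risk_signature <- function(dge_fail, dge_rr, module_genes,
                                 fdr_threshold = 0.05,
                                 module_direction = c("down", "up")) {
  module_direction <- match.arg(module_direction)
  sig1 <- dge_fail[dge_fail$q < fdr_threshold & dge_fail$log2fc != 0, ]
  sig2 <- dge_rr[dge_rr$q < fdr_threshold & dge_rr$log2fc != 0, ]
  common <- intersect(sig1$gene_id, sig2$gene_id)
  s1 <- sign(sig1$log2fc[match(common, sig1$gene_id)])
  s2 <- sign(sig2$log2fc[match(common, sig2$gene_id)])
  concordant <- common[s1 == s2]
  n_discordant <- sum(s1 != s2)
  dir1 <- ifelse(sig1$log2fc[match(concordant, sig1$gene_id)] > 0, "up", "down")
  sig <- tibble::tibble(gene_id = concordant, direction = as.character(dir1),
                        provenance = rep("intersection", length(concordant)))
  extra <- setdiff(module_genes, concordant)
  sig <- dplyr::bind_rows(sig,
    tibble::tibble(gene_id = extra, direction = module_direction,
                   provenance = "module"))
  if (nrow(sig) == 0L) {
    abort("empty signature: no concordant significant genes and no module genes; consider relaxing the FDR threshold")
  }
  class(sig) <- c("gene_signature", class(sig))
  attr(sig, "fdr_threshold") <- fdr_threshold
  attr(sig, "n_discordant") <- n_discordant
  sig
}

#' Read / write a gene signature TSV
#'
#' Two mandatory columns `gene_id` and `direction` plus `provenance`.
#'
#' @param path File path.
#' @return For `read_signature`, a `gene_signature` tibble.
#' @export
read_signature <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("gene_id", "direction") %in% colnames(raw))) {
    abort("signature file needs columns gene_id and direction")
  }
  if (!all(raw$direction %in% c("up", "down"))) abort("direction must be 'up' or 'down'")
  sig <- tibble::tibble(gene_id = raw$gene_id, direction = raw$direction,
                        provenance = raw$provenance %||% NA_character_)
  class(sig) <- c("gene_signature", class(sig))
  sig
}

#' @rdname read_signature
#' @param sig A `gene_signature`.
#' @export
write_signature <- function(sig, path) {
  readr::write_tsv(tibble::as_tibble(sig[, c("gene_id", "direction", "provenance")]), path)
  invisible(path)
}

# bidirectional rank normalization for one direction:
# (mean rank - min possible) / (max possible - min possible) - 0.5
rank_direction_score <- function(ranks, set_idx, n) {
  s <- length(set_idx)
  mean_rank <- mean(ranks[set_idx])
  minp <- (s + 1) / 2
  maxp <- (2 * n - s + 1) / 2
  (mean_rank - minp) / (maxp - minp) - 0.5
}

#' Rank-based bidirectional single-sample signature score
#'
#' For each sample all genes are ranked ascending (average ranks on ties).
#' The up-gene component is the normalized mean rank of the up set,
#' `(meanrank - (s+1)/2) / (n - s) - 0.5`, so a sample expressing the up
#' genes above all others scores +0.5; the down component is computed
#' identically on descending ranks. The totalscore is their sum, bounded in
#' `[-1, 1]` for a bidirectional signature, and is invariant to any
#' monotone transform of a sample's expression values. A z-scaled
#' totalscore over the scored cohort is returned alongside.
#'
#' Signature genes absent from the matrix are dropped; the retained
#' fraction is reported in the `"coverage"` attribute.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sig A `gene_signature`.
#' @return A tibble of class `sample_scores`: `sample_id`, `totalscore`,
#'   `z`.
#' @export
total_score <- function(expr, sig) {
  x <- unclass(expr)
  n <- nrow(x)
  if (n < 2L) abort("expression matrix needs at least 2 genes for ranking")
  up <- intersect(sig$gene_id[sig$direction == "up"], rownames(x))
  down <- intersect(sig$gene_id[sig$direction == "down"], rownames(x))
  if (length(up) + length(down) == 0L) abort("no signature genes present in the expression matrix")
  coverage <- (length(up) + length(down)) /
    length(unique(sig$gene_id[sig$direction %in% c("up", "down")]))
  up_idx <- match(up, rownames(x)); down_idx <- match(down, rownames(x))
  bidirectional <- length(up) > 0L && length(down) > 0L
  scores <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j], ties.method = "average")
    s_up <- if (length(up_idx) > 0L) rank_direction_score(r, up_idx, n) else 0
    s_down <- if (length(down_idx) > 0L) rank_direction_score(n + 1 - r, down_idx, n) else 0
    s_up + s_down
  }, numeric(1))
  z <- if (sd(scores) > 0) as.numeric(scale(scores)) else rep(NA_real_, length(scores))
  out <- tibble::tibble(sample_id = colnames(x), totalscore = scores, z = z)
  class(out) <- c("sample_scores", class(out))
  attr(out, "coverage") <- coverage
  attr(out, "bidirectional") <- bidirectional
  out
}

#' Stratify scored samples into low / intermediate / high risk
#'
#' Cuts the z-scaled totalscore symmetrically at `+/- sd_cut` standard
#' deviations: above the upper cut is high risk, below the lower cut low
#' risk, anything else (including values exactly on a cut) intermediate.
#'
#' @param scores A [total_score()] result (or any tibble with `sample_id`
#'   and `z`; a `totalscore` column is re-scaled if `z` is absent).
#' @param sd_cut Cut point on the z scale (default 1).
#' @return A tibble of class `risk_groups`: `sample_id`, `z`, `risk` (factor
#'   low < intermediate < high); `sd_cut` kept as attribute.
#' @export
stratify <- function(scores, sd_cut = 1.0) {
  if (nrow(scores) < 3L) abort("stratification needs at least 3 samples")
  z <- if ("z" %in% colnames(scores) && !all(is.na(scores$z))) scores$z else {
    if (sd(scores$totalscore) == 0) abort("scores have zero variance; cannot stratify")
    as.numeric(scale(scores$totalscore))
  }
  if (all(is.na(z))) abort("scores have zero variance; cannot stratify")
  risk <- dplyr::case_when(z > sd_cut ~ "high", z < -sd_cut ~ "low",
                           TRUE ~ "intermediate")
  out <- tibble::tibble(sample_id = scores$sample_id, z = z,
                        risk = factor(risk, levels = c("low", "intermediate", "high")))
  class(out) <- c("risk_groups", class(out))
  attr(out, "sd_cut") <- sd_cut
  out
}
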