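# End-to-end orchestration: discovery on a cohort, application of a frozen
# signature to another cohort, and file emission with a run manifest.

#' Run the full signature-discovery pipeline
#'
#' Executes the complete analysis on an aligned cohort: co-expression
#' network construction and module detection on the newly diagnosed
#' samples, module-trait correlation against the 24-month failure
#' endpoint, selection of the most failure-correlated module, the two
#' differential-expression contrasts (failures vs achievers; relapsed
#' tumors vs achievers), directional signature assembly, rank-based
#' scoring and SD stratification, Kaplan-Meier / log-rank / Cox survival
#' association (unadjusted and IPI/COO-adjusted), mutation candidate
#' filtering and Lasso integration, the union classifier on the top
#' mutation feature, and the cross-classifier agreement matrix.
#'
#' @param cohort A `synthetic_cohort`, a `cohort_bundle`, or a list with
#'   `expression`, `clinical` and optionally `mutations`.
#' @param config A [risk_config()].
#' @param out_dir Optional directory; when given, signature / score /
#'   group / survival / integration / agreement files and a JSON run
#'   manifest are written.
#' @param flag_gene Mutation gene for the union classifier; by default the
#'   strongest nonzero Lasso mutation feature (first candidate gene as
#'   fallback).
#' @return A list of class `risk_discovery` with every stage result and a
#'   `manifest` (config snapshot, seed, stage log).
#' @export
run_discovery <- function(cohort, config = risk_config(), out_dir = NULL,
                          flag_gene = NULL) {
  stopifnot(inherits(config, "risk_config"))
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)
  # stage-tagged failure so a mid-pipeline error names the stage it came from
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s': %s", name, conditionMessage(e)))
    })
  }

  bundle <- stage("align", align_cohort(cohort$expression, cohort$clinical,
                                        cohort$mutations))
  note("align")
  clin <- bundle$clinical
  nd <- clin$sample_id[clin$cohort == "nd"]
  rr <- clin$sample_id[clin$cohort == "rr"]
  if (length(nd) < 20L) abort("discovery needs at least 20 newly diagnosed samples")
  expr_nd <- expression_matrix(unclass(bundle$expression)[, nd, drop = FALSE])

  efs24 <- derive_efs24(clin, config$efs24_horizon)
  note("efs24")

  # co-expression network on nd samples
  sft <- stage("coexpression", pick_soft_threshold(expr_nd, powers = config$soft_power_grid))
  tom <- stage("coexpression", adjacency_tom(expr_nd, sft$power))
  modules <- stage("coexpression",
    detect_modules(tom, min_module_size = config$min_module_size,
                   expr = expr_nd, merge_cor = config$module_merge_cor,
                   cut_quantile = config$cut_quantile))
  eig <- NULL; mtc <- NULL
  if (length(setdiff(unique(modules$module), "grey")) > 0L) {
    eig <- stage("coexpression", module_eigengenes(expr_nd, modules, quiet = TRUE))
    nd_status <- efs24$efs24[match(nd, efs24$sample_id)]
    traits <- tibble::tibble(
      sample_id = nd,
      efs24_fail = ifelse(nd_status == "unevaluable", NA_real_,
                          as.numeric(nd_status == "fail")),
      abc = as.numeric(clin$coo[match(nd, clin$sample_id)] == "ABC"),
      ipi = as.numeric(clin$ipi[match(nd, clin$sample_id)]))
    mtc <- stage("coexpression", module_trait_correlation(eig, traits))
    risk_mod <- stage("coexpression", select_risk_module(mtc, "efs24_fail", modules))
  } else {
    warn("no co-expression modules detected; signature will rely on the contrasts alone")
    risk_mod <- structure(list(module = NA_character_, r = NA_real_,
                               p = NA_real_, genes = character(0)),
                          class = "risk_module")
  }
  note("coexpression")

  # dual differential-expression contrasts
  fail_ids <- efs24$sample_id[efs24$efs24 == "fail" & efs24$sample_id %in% nd]
  achv_ids <- efs24$sample_id[efs24$efs24 == "achieve" & efs24$sample_id %in% nd]
  dge_fail <- stage("dge", differential_expression(bundle$expression, achv_ids,
                                                   fail_ids, d0 = config$d0))
  dge_rr <- stage("dge", differential_expression(bundle$expression, achv_ids, rr,
                                                 d0 = config$d0))
  note("dge")

  # module genes inherit the direction implied by the selected module's
  # failure correlation (negative correlation = lower in failures = "down")
  module_dir <- if (!is.na(risk_mod$r) && risk_mod$r > 0) "up" else "down"
  signature <- stage("signature",
    build_risk_signature(dge_fail, dge_rr, risk_mod$genes,
                         fdr_threshold = config$fdr_threshold,
                         module_direction = module_dir))
  note("signature")

  scores <- stage("scoring", total_score(bundle$expression, signature))
  nd_scores <- scores[scores$sample_id %in% nd, , drop = FALSE]
  nd_scores$z <- as.numeric(scale(nd_scores$totalscore))
  groups <- stage("scoring", stratify(nd_scores, sd_cut = config$sd_cut))
  note("scoring")

  surv <- stage("survival",
    survival_association(clin[match(nd, clin$sample_id), ], groups))
  note("survival")

  integration <- NULL
  agreement <- NULL
  if (!is.null(bundle$mutations) && nrow(bundle$mutations) > 0L) {
    panel <- sort(unique(bundle$mutations$gene))
    mm <- binarize_mutations(bundle$mutations, panel, nd)
    candidates <- filter_candidate_genes(mm, efs24,
                                         freq_min = config$mutation_freq_min,
                                         p_max = config$mutation_p_max)
    cand_genes <- candidates$gene[candidates$candidate]
    lasso <- NULL
    if (length(cand_genes) > 0L) {
      lasso <- lasso_integration(groups, mm, efs24, candidates = cand_genes,
                                 fold_seed = config$random_seed)
    }
    if (is.null(flag_gene)) {
      mut_feats <- if (!is.null(lasso)) {
        sel <- lasso$selected[lasso$selected$feature %in% colnames(mm), , drop = FALSE]
        sel$feature[order(-abs(sel$coefficient))]
      } else character(0)
      flag_gene <- c(mut_feats, cand_genes, colnames(mm))[1L]
    }
    icall <- integrated_call(groups, mm, flag_gene, efs24)
    integration <- list(candidates = candidates, lasso = lasso,
                        integrated = icall, flag_gene = flag_gene)
    note("integration")

    ev <- efs24[efs24$sample_id %in% nd & efs24$efs24 != "unevaluable", ]
    ind <- tibble::tibble(
      efs24_fail = as.integer(ev$efs24 == "fail"),
      expression_high = as.integer(
        icall$calls$expression_high[match(ev$sample_id, icall$calls$sample_id)]),
      integrated_high = as.integer(
        icall$calls$integrated_high[match(ev$sample_id, icall$calls$sample_id)]),
      flag_mutated = as.integer(
        icall$calls$mutated[match(ev$sample_id, icall$calls$sample_id)]))
    agreement <- suppressWarnings(agreement_matrix(ind))
    note("agreement")
  }

  manifest <- list(
    config = unclass(config), seed = config$random_seed,
    n_nd = length(nd), n_rr = length(rr),
    soft_power = sft$power, risk_module = risk_mod$module,
    n_signature_genes = nrow(signature), stages = stages,
    timestamp_free = TRUE)

  res <- structure(
    list(bundle = bundle, efs24 = efs24, soft_threshold = sft,
         modules = modules, eigengenes = eig, module_trait = mtc,
         risk_module = risk_mod, dge_fail = dge_fail, dge_rr = dge_rr,
         signature = signature, scores = nd_scores, groups = groups,
         survival = surv, integration = integration, agreement = agreement,
         config = config, manifest = manifest),
    class = "risk_discovery")
  if (!is.null(out_dir)) write_discovery(res, out_dir)
  res
}

# Cox and KM association of the risk strata with EFS and OS
survival_association <- function(clin, groups) {
  r <- groups$risk[match(clin$sample_id, groups$sample_id)]
  covars_un <- data.frame(risk = r)
  covars_adj <- data.frame(risk = r, ipi = clin$ipi, coo = clin$coo)
  ok_adj <- stats::complete.cases(covars_adj)
  list(
    efs_cox = cox_model(clin$efs_time, clin$efs_event, covars_un),
    efs_cox_adjusted = cox_model(clin$efs_time[ok_adj], clin$efs_event[ok_adj],
                                 covars_adj[ok_adj, , drop = FALSE]),
    os_cox = cox_model(clin$os_time, clin$os_event, covars_un),
    efs_km = kaplan_meier(clin$efs_time, clin$efs_event, r),
    os_km = kaplan_meier(clin$os_time, clin$os_event, r))
}

#' Write discovery artifacts to a directory
#'
#' Emits `signature.tsv`, `scores.tsv`, `groups.tsv`, `module_assignment.tsv`,
#' `module_trait.tsv`, `survival.json`, `integrated.json`, `kappa.tsv` and
#' `manifest.json`. Deterministic given the same cohort, config and seed.
#'
#' @param res A [run_discovery()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_discovery <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_signature(res$signature, file.path(out_dir, "signature.tsv"))
  readr::write_tsv(tibble::as_tibble(res$scores), file.path(out_dir, "scores.tsv"))
  readr::write_tsv(tibble::as_tibble(res$groups), file.path(out_dir, "groups.tsv"))
  readr::write_tsv(tibble::as_tibble(res$modules[, c("gene_id", "module")]),
                   file.path(out_dir, "module_assignment.tsv"))
  if (!is.null(res$module_trait)) {
    readr::write_tsv(tibble::as_tibble(res$module_trait),
                     file.path(out_dir, "module_trait.tsv"))
  }
  surv_json <- list(
    efs_unadjusted = res$survival$efs_cox$tidy,
    efs_adjusted = res$survival$efs_cox_adjusted$tidy,
    os_unadjusted = res$survival$os_cox$tidy,
    efs_logrank = res$survival$efs_km$logrank)
  jsonlite::write_json(surv_json, file.path(out_dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$integration)) {
    int_json <- list(
      flag_gene = res$integration$flag_gene,
      candidates = res$integration$candidates,
      lasso_selected = if (!is.null(res$integration$lasso)) res$integration$lasso$selected,
      metrics = res$integration$integrated$metrics)
    jsonlite::write_json(int_json, file.path(out_dir, "integrated.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(res$agreement)) {
    readr::write_tsv(tidy(res$agreement), file.path(out_dir, "kappa.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Apply a frozen signature to a new cohort
#'
#' Scores the cohort with the signature, re-scales internally, stratifies
#' at the configured SD cut, and reports Kaplan-Meier and Cox association
#' with event-free survival. The fraction of signature genes present on
#' the new platform is checked: below 50% a warning is raised, below 10%
#' the application aborts.
#'
#' @param signature A `gene_signature` (or path to a signature TSV).
#' @param expr Expression matrix of the new cohort.
#' @param clin Clinical tibble of the new cohort.
#' @param config A [risk_config()].
#' @return A list of class `risk_application`: `scores`, `groups`,
#'   `coverage`, `efs_cox`, `efs_km`.
#' @export
run_apply <- function(signature, expr, clin, config = risk_config()) {
  if (is.character(signature)) signature <- read_signature(signature)
  clin <- validate_clinical(clin)
  present <- mean(unique(signature$gene_id) %in% rownames(expr))
  if (present < 0.10) {
    abort(sprintf("only %.0f%% of signature genes present; cannot apply", 100 * present))
  }
  if (present < 0.50) {
    warn(sprintf("only %.0f%% of signature genes present in the new cohort", 100 * present))
  }
  scores <- total_score(expr, signature)
  groups <- stratify(scores, sd_cut = config$sd_cut)
  ids <- intersect(clin$sample_id, groups$sample_id)
  cl <- clin[match(ids, clin$sample_id), ]
  r <- groups$risk[match(ids, groups$sample_id)]
  efs_cox <- if (nlevels(droplevels(r)) >= 2L && sum(cl$efs_event) >= 2L) {
    cox_model(cl$efs_time, cl$efs_event, data.frame(risk = r))
  } else NULL
  efs_km <- kaplan_meier(cl$efs_time, cl$efs_event, r)
  structure(list(scores = scores, groups = groups, coverage = present,
                 efs_cox = efs_cox, efs_km = efs_km),
            class = "risk_application")
}

#' @export
print.risk_discovery <- function(x, ...) {
  cat("Risk-signature discovery run\n")
  cat(sprintf("  samples: %d nd + %d rr; soft power %d\n",
              x$manifest$n_nd, x$manifest$n_rr, x$manifest$soft_power))
  cat(sprintf("  modules: %d (+ grey); risk module '%s' (r = %.3f with EFS24 failure)\n",
              length(setdiff(unique(x$modules$module), "grey")),
              x$risk_module$module, x$risk_module$r))
  cat(sprintf("  signature: %d genes (%d up, %d down)\n", nrow(x$signature),
              sum(x$signature$direction == "up"), sum(x$signature$direction == "down")))
  cat(sprintf("  risk groups: %s\n",
              paste(sprintf("%s=%d", levels(x$groups$risk), table(x$groups$risk)),
                    collapse = ", ")))
  invisible(x)
}
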