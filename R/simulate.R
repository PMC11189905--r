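#' Design of a synthetic lymphoma cohort
#'
#' Parameterizes the generator in [simulate_cohort()]. The defaults emulate
#' the structure of a real-world discovery setting: roughly 320 newly
#' diagnosed and 140 relapsed/refractory tumors, 2000 genes of which six
#' planted co-expression modules occupy 550, one module (the "risk" module)
#' downregulated in samples prone to early failure, exponential event times
#' with class-specific monthly hazards calibrated so that about a quarter of
#' newly diagnosed cases fail the 24-month event-free horizon, and a small
#' mutation panel in which one ARID1A-like gene carries failure signal
#' partially independent of the expression modules.
#'
#' @param n_nd,n_rr Newly diagnosed / relapsed-refractory sample counts.
#' @param n_genes Total genes simulated.
#' @param module_sizes Sizes of the planted co-expression modules; must sum
#'   to at most `n_genes`.
#' @param risk_module_index Which planted module carries the outcome signal.
#' @param risk_effect Standardized shift of the risk-module latent factor in
#'   failure-prone samples (negative = downregulated in failures).
#' @param de_gene_frac,de_log2fc Fraction of background genes given a direct
#'   differential-expression offset (random sign, magnitude `de_log2fc`) in
#'   failure-prone and relapsed samples.
#' @param hazard_low,hazard_int,hazard_high Monthly exponential event
#'   hazards for the three latent risk classes.
#' @param class_probs Marginal probabilities of the low / intermediate /
#'   high latent risk classes.
#' @param censor_admin Administrative censoring time in months.
#' @param mutation_genes Tibble with columns `gene`, `freq` (baseline
#'   mutation frequency among non-failures) and `or` (odds ratio of mutation
#'   given EFS24 failure). The default panel plants `ARID1A` at 10%
#'   frequency with OR 3 plus weaker and null genes.
#' @param noise_sd Residual expression noise standard deviation.
#' @param loading_range Range of per-gene loadings on the module factor.
#' @param seed Master seed; all randomness flows from it through named
#'   substreams.
#' @return A validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_nd = 320L, n_rr = 140L, n_genes = 2000L,
                              module_sizes = c(150L, 120L, 100L, 80L, 60L, 40L),
                              risk_module_index = 6L, risk_effect = -1.0,
                              de_gene_frac = 0.05, de_log2fc = 1.0,
                              hazard_low = 0.003, hazard_int = 0.010,
                              hazard_high = 0.060,
                              class_probs = c(0.16, 0.68, 0.16),
                              censor_admin = 120,
                              mutation_genes = default_mutation_panel(),
                              noise_sd = 0.6, loading_range = c(0.7, 1.3),
                              seed = 1L) {
  stopifnot(n_nd > 0, n_rr >= 0, n_genes >= 2)
  if (any(module_sizes < 2)) abort("module sizes must be at least 2")
  if (sum(module_sizes) > n_genes) abort("module sizes exceed the number of genes")
  if (length(module_sizes) == 0L) {
    risk_module_index <- 0L  # no planted modules, no risk module
  } else if (risk_module_index < 1 || risk_module_index > length(module_sizes)) {
    abort("risk_module_index out of range")
  }
  if (any(c(hazard_low, hazard_int, hazard_high) <= 0)) abort("hazards must be positive")
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs <= 0)) {
    abort("class_probs must be positive and sum to 1")
  }
  if (censor_admin <= 0) abort("censor_admin must be positive")
  mutation_genes <- tibble::as_tibble(mutation_genes)
  stopifnot(all(c("gene", "freq", "or") %in% colnames(mutation_genes)))
  if (any(mutation_genes$freq <= 0 | mutation_genes$freq >= 1)) {
    abort("mutation frequencies must be in (0, 1)")
  }
  structure(
    list(n_nd = as.integer(n_nd), n_rr = as.integer(n_rr),
         n_genes = as.integer(n_genes),
         module_sizes = as.integer(module_sizes),
         n_modules = length(module_sizes),
         risk_module_index = as.integer(risk_module_index),
         risk_effect = risk_effect, de_gene_frac = de_gene_frac,
         de_log2fc = de_log2fc,
         hazards = c(low = hazard_low, intermediate = hazard_int, high = hazard_high),
         class_probs = setNames(class_probs, c("low", "intermediate", "high")),
         censor_admin = censor_admin, mutation_genes = mutation_genes,
         noise_sd = noise_sd, loading_range = loading_range,
         seed = as.integer(seed)),
    class = "simulation_design")
}

#' Default mutation panel for the synthetic cohort
#'
#' Lymphoma-style gene names; `ARID1A` is the single planted outcome-linked
#' gene (baseline frequency 10%, odds ratio 3 for failure, independent of
#' the expression modules given failure status); the remainder are null
#' passengers at realistic frequencies.
#'
#' @return A tibble with columns `gene`, `freq`, `or`.
#' @export
default_mutation_panel <- function() {
  tibble::tibble(
    gene = c("ARID1A", "TP53", "CREBBP", "KMT2D", "BCL2", "PIM1",
             "MYD88", "CARD11", "EZH2", "SOCS1", "BTG2", "TNFRSF14"),
    freq = c(0.10, 0.20, 0.15, 0.25, 0.12, 0.18, 0.08, 0.07, 0.06, 0.10, 0.09, 0.11),
    or   = c(3.0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  )
}

#' Simulate a synthetic lymphoma cohort
#'
#' Generates expression, clinical and mutation tables with known ground
#' truth under a spiked latent-factor model: gene `g` in module `m` is
#' `loading_g * f_m + N(0, noise_sd)` with per-sample module factors
#' `f_m ~ N(0, 1)`; the risk module's factor is shifted by `risk_effect` in
#' latent high-risk (failure-prone) samples and in all relapsed/refractory
#' samples. A random subset of background genes additionally receives a
#' fixed-sign offset in those same samples. Event times are exponential with
#' the sample's latent-class hazard, administratively censored; mutations
#' are Bernoulli with log-odds tied to the realized 24-month failure status
#' through each panel gene's configured odds ratio. The whole cohort is a
#' deterministic function of the design (including its seed).
#'
#' @param design A [simulation_design()].
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (genes x samples matrix), `clinical` (tibble), `mutations` (tibble of
#'   records for newly diagnosed samples), `truth` (list with per-sample and
#'   per-gene ground-truth tibbles) and `design`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  d <- design
  n <- d$n_nd + d$n_rr
  sample_ids <- c(sprintf("ND%03d", seq_len(d$n_nd)),
                  sprintf("RR%03d", seq_len(d$n_rr)))
  cohort_lab <- c(rep("nd", d$n_nd), rep("rr", d$n_rr))
  gene_ids <- sprintf("G%04d", seq_len(d$n_genes))

  # gene -> module map; module genes occupy the head of the gene list
  module_of <- rep(0L, d$n_genes)
  pos <- 1L
  for (m in seq_len(d$n_modules)) {
    module_of[pos:(pos + d$module_sizes[m] - 1L)] <- m
    pos <- pos + d$module_sizes[m]
  }

  # latent risk class for nd samples; rr samples are failure-prone by design
  true_class <- with_substream(d$seed, "class", {
    cls <- sample(names(d$class_probs), d$n_nd, replace = TRUE, prob = d$class_probs)
    c(cls, rep("high", d$n_rr))
  })
  fail_prone <- true_class == "high" | cohort_lab == "rr"

  # survival for nd samples (rr tumors are sampled at relapse; short times)
  surv <- with_substream(d$seed, "survival", {
    haz <- d$hazards[true_class]
    efs_raw <- rexp(n, rate = haz)
    os_raw <- efs_raw + rexp(n, rate = 0.02)
    tibble::tibble(
      efs_time = pmin(efs_raw, d$censor_admin),
      efs_event = efs_raw <= d$censor_admin,
      os_time = pmin(os_raw, d$censor_admin),
      os_event = os_raw <= d$censor_admin
    )
  })
  efs24_true <- surv$efs_event & surv$efs_time <= 24

  # expression: module factors + loadings + background DE + noise
  loadings <- with_substream(d$seed, "loadings",
    runif(d$n_genes, d$loading_range[1L], d$loading_range[2L]))
  factors <- with_substream(d$seed, "factors",
    matrix(rnorm(d$n_modules * n), nrow = d$n_modules))
  if (d$risk_module_index > 0L) {
    factors[d$risk_module_index, fail_prone] <-
      factors[d$risk_module_index, fail_prone] + d$risk_effect
  }

  n_de <- round(d$de_gene_frac * d$n_genes)
  background <- which(module_of == 0L)
  de_info <- with_substream(d$seed, "de_genes", {
    idx <- sample(background, min(n_de, length(background)))
    sign <- sample(c(-1, 1), length(idx), replace = TRUE)
    list(idx = idx, sign = sign)
  })

  expr <- with_substream(d$seed, "noise", {
    e <- matrix(rnorm(d$n_genes * n, sd = d$noise_sd), nrow = d$n_genes)
    inmod <- module_of > 0L
    if (any(inmod)) {
      e[inmod, ] <- e[inmod, ] +
        loadings[inmod] * factors[module_of[inmod], , drop = FALSE]
    }
    if (length(de_info$idx) > 0L) {
      e[de_info$idx, fail_prone] <- e[de_info$idx, fail_prone] +
        de_info$sign * d$de_log2fc
    }
    e + 8  # shift to a plausible log-expression location
  })
  rownames(expr) <- gene_ids
  colnames(expr) <- sample_ids

  # clinical covariates, mildly informative of the latent class
  covars <- with_substream(d$seed, "covariates", {
    p_ipi <- c(low = 0.30, intermediate = 0.42, high = 0.55)[true_class]
    ipi <- rbinom(n, 5L, p_ipi)
    coo <- character(n)
    for (i in seq_len(n)) {
      pr <- if (fail_prone[i]) c(0.50, 0.35, 0.15) else c(0.30, 0.55, 0.15)
      coo[i] <- sample(c("ABC", "GCB", "Unclassified"), 1L, prob = pr)
    }
    tibble::tibble(ipi = as.integer(ipi), coo = coo)
  })

  clinical <- tibble::tibble(
    sample_id = sample_ids, efs_time = surv$efs_time, efs_event = surv$efs_event,
    os_time = surv$os_time, os_event = surv$os_event,
    ipi = covars$ipi, coo = covars$coo, cohort = cohort_lab)

  # mutations for nd samples, conditional on realized EFS24 failure
  mut <- with_substream(d$seed, "mutations", {
    nd_idx <- which(cohort_lab == "nd")
    recs <- purrr::pmap_dfr(d$mutation_genes, function(gene, freq, or) {
      lp <- qlogis(freq) + log(or) * efs24_true[nd_idx]
      hit <- rbinom(length(nd_idx), 1L, plogis(lp)) == 1L
      tibble::tibble(sample_id = sample_ids[nd_idx][hit], gene = gene,
                     variant_class = "Missense_Mutation")
    })
    recs[order(recs$sample_id, recs$gene), ]
  })

  module_label <- ifelse(module_of == 0L, "background", paste0("sim", module_of))
  truth <- list(
    samples = tibble::tibble(
      sample_id = sample_ids, cohort = cohort_lab, true_class = true_class,
      fail_prone = fail_prone, efs24_fail = efs24_true,
      risk_factor = if (d$risk_module_index > 0L) factors[d$risk_module_index, ]
                    else rep(NA_real_, n)),
    genes = tibble::tibble(
      gene_id = gene_ids, module = module_label,
      is_risk_module = d$risk_module_index > 0L & module_of == d$risk_module_index,
      is_de = seq_len(d$n_genes) %in% de_info$idx,
      de_sign = ifelse(seq_len(d$n_genes) %in% de_info$idx,
                       de_info$sign[match(seq_len(d$n_genes), de_info$idx)], 0),
      loading = ifelse(module_of > 0L, loadings, NA_real_))
  )

  structure(
    list(expression = expression_matrix(expr), clinical = clinical,
         mutations = mut, truth = truth, design = d),
    class = "synthetic_cohort")
}

#' Per-sample ground-truth summary of a synthetic cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A tibble with one row per simulated sample: cohort label, latent
#'   risk class, realized 24-month failure status and the risk-module latent
#'   factor, sorted by `sample_id`.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dplyr::arrange(cohort$truth$samples, .data$sample_id)
}

#' Gene-level ground truth of a synthetic cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A tibble with one row per gene: planted module label,
#'   differential-expression status and factor loading.
#' @export
truth_genes <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth$genes
}

#' Write a synthetic cohort as TSV files
#'
#' Emits `expression.tsv`, `clinical.tsv`, `mutations.tsv`,
#' `truth_samples.tsv` and `truth_genes.tsv` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(dplyr::mutate(cohort$clinical,
                                 efs_event = as.integer(.data$efs_event),
                                 os_event = as.integer(.data$os_event)),
                   file.path(dir, "clinical.tsv"))
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(cohort$truth$samples, file.path(dir, "truth_samples.tsv"))
  readr::write_tsv(cohort$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
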