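#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream stage assumes: unique gene and
#' sample identifiers, no missing or non-finite values, and at least two
#' genes and two samples. Values are expected to be normalized, log-scale
#' expression; the package performs no normalization of its own.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @return The validated matrix, invisibly classed as `expr_matrix`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("expression values must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    abort("expression matrix needs at least 2 genes and 2 samples")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene identifiers in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample identifiers in expression matrix")
  }
  if (any(!is.finite(values))) {
    abort("expression matrix contains missing or non-finite values")
  }
  class(values) <- c("expr_matrix", class(values))
  invisible(values)
}

#' Read a gene-by-sample expression TSV
#'
#' The file must have a header row of sample identifiers and gene symbols in
#' the first column. Every data cell must parse as a number; a non-numeric
#' cell (including literal `NA`) is a parse error naming the offending gene
#' and sample. Duplicate gene rows are collapsed by keeping the row with the
#' highest mean expression; collapsed genes are recorded in the
#' `"collapsed_genes"` attribute.
#'
#' @param path Path to a tab-separated file.
#' @return A validated `expr_matrix` (genes x samples).
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("expression TSV needs a gene column plus sample columns")
  genes <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample identifiers in header: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-numeric expression value '%s' at gene '%s', sample '%s'",
      cells[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  rownames(num) <- genes
  colnames(num) <- sample_ids
  collapsed <- character(0)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    means <- rowMeans(num)
    keep <- rep(TRUE, nrow(num))
    for (g in dup) {
      idx <- which(genes == g)
      keep[idx] <- FALSE
      keep[idx[which.max(means[idx])]] <- TRUE
    }
    collapsed <- dup
    num <- num[keep, , drop = FALSE]
  }
  out <- expression_matrix(num)
  attr(out, "collapsed_genes") <- collapsed
  out
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; values are written with full double
#' precision so a write/read round trip reproduces them exactly.
#'
#' @param expr Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(unclass(expr), rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

clinical_required_cols <- c("sample_id", "efs_time", "efs_event",
                            "os_time", "os_event", "ipi", "coo", "cohort")
coo_levels <- c("ABC", "GCB", "Unclassified")

#' Read a per-sample clinical table
#'
#' Required columns: `sample_id`, `efs_time`, `efs_event`, `os_time`,
#' `os_event`, `ipi`, `coo`, `cohort`. Times are months (decimals allowed),
#' events are 0/1 or logical, `ipi` is 0-5 or missing, `coo` one of ABC /
#' GCB / Unclassified (anything else becomes missing, with a warning giving
#' the count), `cohort` is `nd` (newly diagnosed) or `rr`
#' (relapsed/refractory) and must be present for every sample.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble, one row per sample; the number of unrecognized
#'   cell-of-origin labels is stored in attribute `"n_coo_unknown"`.
#' @export
read_clinical <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  missing_cols <- setdiff(clinical_required_cols, colnames(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("clinical table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  clin <- tibble::tibble(
    sample_id = as.character(raw$sample_id),
    efs_time = as.numeric(raw$efs_time),
    efs_event = as.logical(as.integer(raw$efs_event)),
    os_time = as.numeric(raw$os_time),
    os_event = as.logical(as.integer(raw$os_event)),
    ipi = suppressWarnings(as.integer(raw$ipi)),
    coo = as.character(raw$coo),
    cohort = as.character(raw$cohort)
  )
  validate_clinical(clin)
}

#' Validate a clinical table
#'
#' @param clin A data frame with the columns documented in [read_clinical()].
#' @return The validated tibble.
#' @export
validate_clinical <- function(clin) {
  clin <- tibble::as_tibble(clin)
  missing_cols <- setdiff(clinical_required_cols, colnames(clin))
  if (length(missing_cols) > 0L) {
    abort(sprintf("clinical table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(clin$sample_id)) abort("duplicate sample_id in clinical table")
  if (any(clin$efs_time < 0, na.rm = TRUE) || any(clin$os_time < 0, na.rm = TRUE)) {
    abort("survival times must be non-negative")
  }
  if (any(is.na(clin$cohort)) || !all(clin$cohort %in% c("nd", "rr"))) {
    abort("cohort must be 'nd' or 'rr' for every sample")
  }
  if (any(!is.na(clin$ipi) & (clin$ipi < 0L | clin$ipi > 5L))) {
    abort("ipi must be an integer in 0-5 or missing")
  }
  unknown <- !is.na(clin$coo) & !(clin$coo %in% coo_levels)
  if (any(unknown)) {
    warn(sprintf("%d unrecognized cell-of-origin label(s) set to missing", sum(unknown)))
    clin$coo[unknown] <- NA_character_
  }
  attr(clin, "n_coo_unknown") <- sum(unknown)
  clin
}

#' Read a mutation call table (MAF subset)
#'
#' Columns: `sample_id`, `gene`, `variant_class`. A (sample, gene) pair may
#' repeat across variant classes; downstream binarization collapses to a
#' single mutated indicator per gene per sample.
#'
#' @param path Path to a tab-separated file.
#' @param panel Optional character vector restricting genes to a declared
#'   analysis panel; rows outside the panel are dropped with a warning.
#' @return A tibble of mutation records.
#' @export
read_mutations <- function(path, panel = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "gene", "variant_class")
  missing_cols <- setdiff(need, colnames(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("mutation table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  muts <- tibble::as_tibble(raw[need])
  if (!is.null(panel)) {
    off <- !(muts$gene %in% panel)
    if (any(off)) {
      warn(sprintf("%d mutation record(s) outside the analysis panel dropped", sum(off)))
      muts <- muts[!off, , drop = FALSE]
    }
  }
  muts
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (the gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1L]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT")
  if (any(lengths(sets) == 0L)) abort("empty gene set in GMT")
  sets
}

#' Align expression, clinical and mutation data on shared samples
#'
#' Restricts all tables to the intersection of sample identifiers (exact,
#' case-sensitive match) in the order the expression matrix lists them, and
#' reports which identifiers each source lost. Aligning an already aligned
#' bundle is a no-op.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clin Clinical tibble.
#' @param muts Optional mutation tibble; records for samples outside the
#'   intersection are dropped.
#' @return A list of class `cohort_bundle` with elements `expression`,
#'   `clinical`, `mutations` (possibly `NULL`) and `dropped`, a named list of
#'   identifiers removed from each source.
#' @export
align_cohort <- function(expr, clin, muts = NULL) {
  clin <- validate_clinical(clin)
  shared <- intersect(colnames(expr), clin$sample_id)
  if (length(shared) == 0L) abort("no samples shared between expression and clinical data")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  dropped <- list(
    expression = setdiff(colnames(expr), shared),
    clinical = setdiff(clin$sample_id, shared)
  )
  expr2 <- unclass(expr)[, shared, drop = FALSE]
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  muts2 <- NULL
  if (!is.null(muts)) {
    dropped$mutations <- setdiff(unique(muts$sample_id), shared)
    muts2 <- muts[muts$sample_id %in% shared, , drop = FALSE]
  }
  structure(
    list(expression = expression_matrix(expr2), clinical = clin2,
         mutations = muts2, dropped = dropped),
    class = "cohort_bundle")
}

#' Analysis configuration
#'
#' Collects every tunable threshold of the discovery pipeline in one place,
#' with the defaults used throughout: signature genes enter at FDR < 0.05,
#' risk strata are cut at +/- 1 SD of the scaled totalscore, mutation
#' candidates must have frequency >= 5%, odds ratio > 1 and chi-square
#' P <= 0.15 for association with failure at the 24-month event-free
#' horizon.
#'
#' @param fdr_threshold FDR cutoff for the differential-expression contrasts.
#' @param sd_cut Stratification cut point on the z-scaled totalscore.
#' @param mutation_freq_min Minimum mutation frequency for candidate genes.
#' @param mutation_p_max Maximum chi-square p for candidate genes.
#' @param efs24_horizon Event-free survival horizon in months.
#' @param random_seed Master seed; every stochastic stage draws a named
#'   substream from it.
#' @param soft_power_grid Candidate soft-threshold powers.
#' @param min_module_size Smallest co-expression module retained.
#' @param module_merge_cor Eigengene correlation above which modules merge.
#' @param cut_quantile Fraction of the dendrogram height at which branches
#'   are cut.
#' @param d0 Prior degrees of freedom for the moderated-t variance shrinkage.
#' @return A validated list of class `risk_config`.
#' @export
risk_config <- function(fdr_threshold = 0.05, sd_cut = 1.0,
                        mutation_freq_min = 0.05, mutation_p_max = 0.15,
                        efs24_horizon = 24, random_seed = 1L,
                        soft_power_grid = c(1:10, 12L, 14L, 16L),
                        min_module_size = 30L, module_merge_cor = 0.75,
                        cut_quantile = 0.99, d0 = 4) {
  assert_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  assert_scalar_number(sd_cut, "sd_cut", 0, Inf)
  assert_scalar_number(mutation_freq_min, "mutation_freq_min", 0, 1)
  assert_scalar_number(mutation_p_max, "mutation_p_max", 0, 1)
  assert_scalar_number(efs24_horizon, "efs24_horizon", 1e-9, Inf)
  assert_scalar_number(random_seed, "random_seed", -2^31, 2^31)
  assert_scalar_number(min_module_size, "min_module_size", 2, Inf)
  assert_scalar_number(module_merge_cor, "module_merge_cor", 0, 1)
  assert_scalar_number(cut_quantile, "cut_quantile", 0, 1)
  assert_scalar_number(d0, "d0", 0, Inf)
  if (!is.numeric(soft_power_grid) || any(soft_power_grid < 1)) {
    abort("soft_power_grid must be powers >= 1")
  }
  structure(
    list(fdr_threshold = fdr_threshold, sd_cut = sd_cut,
         mutation_freq_min = mutation_freq_min, mutation_p_max = mutation_p_max,
         efs24_horizon = efs24_horizon, random_seed = as.integer(random_seed),
         soft_power_grid = as.integer(soft_power_grid),
         min_module_size = as.integer(min_module_size),
         module_merge_cor = module_merge_cor, cut_quantile = cut_quantile,
         d0 = d0),
    class = "risk_config")
}
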