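# Cohen's kappa and the pairwise classifier agreement matrix.

#' Cohen's kappa for two binary labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from the marginals. The large-sample
#' standard error `sqrt(p_o (1 - p_o)) / ((1 - p_e) sqrt(n))` gives a
#' normal-approximation 95% confidence interval. A constant labeling makes
#' kappa undefined; a flagged missing result is returned with a warning.
#'
#' @param x,y Equal-length binary (logical or 0/1) label vectors; pairs
#'   with a missing value are dropped.
#' @return A one-row tibble of class `kappa_result`: `kappa`, `se`,
#'   `ci_low`, `ci_high`, `n`, `undefined`.
#' @export
cohens_kappa <- function(x, y) {
  if (length(x) != length(y)) abort("labelings must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- as.integer(as.logical(x[keep])); y <- as.integer(as.logical(y[keep]))
  n <- length(x)
  if (n < 2L) abort("need at least 2 paired labels")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warn("constant labeling: kappa undefined")
    return(structure(tibble::tibble(kappa = NA_real_, se = NA_real_,
                                    ci_low = NA_real_, ci_high = NA_real_,
                                    n = n, undefined = TRUE),
                     class = c("kappa_result", class(tibble::tibble()))))
  }
  p_o <- mean(x == y)
  p_e <- mean(x) * mean(y) + (1 - mean(x)) * (1 - mean(y))
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o)) / ((1 - p_e) * sqrt(n))
  out <- tibble::tibble(kappa = kappa, se = se,
                        ci_low = kappa - qnorm(0.975) * se,
                        ci_high = kappa + qnorm(0.975) * se,
                        n = n, undefined = FALSE)
  class(out) <- c("kappa_result", class(out))
  out
}

#' Pairwise agreement matrix over classifier indicator columns
#'
#' Computes Cohen's kappa for every pair of binary indicator columns
#' (pairwise-complete samples), with a signed significance mask: +1 when
#' the 95% confidence interval lies above 0, -1 when below, 0 otherwise.
#' Columns with fewer than 2 informative (non-constant, non-missing)
#' values are excluded with a warning.
#'
#' @param indicators A data frame or matrix of per-sample binary columns,
#'   one per classifier category.
#' @return A list of class `agreement_matrix`: `kappa`, `ci_low`,
#'   `ci_high`, `significant` (signed), all symmetric with unit/NA
#'   diagonals, plus `excluded` column names.
#' @export
agreement_matrix <- function(indicators) {
  m <- as.matrix(as.data.frame(indicators))
  if (ncol(m) < 2L) abort("need at least 2 classifier columns")
  informative <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[!is.na(m[, j]), j]
    length(v) >= 2L && length(unique(v)) >= 2L
  }, logical(1))
  if (any(!informative)) {
    warn(sprintf("excluding constant or empty column(s): %s",
                 paste(colnames(m)[!informative], collapse = ", ")))
    m <- m[, informative, drop = FALSE]
  }
  if (ncol(m) < 2L) abort("fewer than 2 informative classifier columns remain")
  k <- ncol(m)
  nm <- colnames(m)
  kap <- lo <- hi <- sig <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(kap) <- 1; diag(sig) <- 1
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      res <- suppressWarnings(cohens_kappa(m[, i], m[, j]))
      kap[i, j] <- kap[j, i] <- res$kappa
      lo[i, j] <- lo[j, i] <- res$ci_low
      hi[i, j] <- hi[j, i] <- res$ci_high
      s <- if (is.na(res$kappa)) NA_real_
           else if (res$ci_low > 0) 1 else if (res$ci_high < 0) -1 else 0
      sig[i, j] <- sig[j, i] <- s
    }
  }
  structure(list(kappa = kap, ci_low = lo, ci_high = hi, significant = sig,
                 excluded = colnames(as.data.frame(indicators))[!informative]),
            class = "agreement_matrix")
}

#' @export
tidy.agreement_matrix <- function(x, ...) {
  tibble::as_tibble(x$kappa, rownames = "classifier_1") |>
    tidyr::pivot_longer(-"classifier_1", names_to = "classifier_2",
                        values_to = "kappa") |>
    dplyr::mutate(
      ci_low = as.vector(t(x$ci_low)),
      ci_high = as.vector(t(x$ci_high)),
      significant = as.vector(t(x$significant)))
}
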