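#' Winsorization fences at 3 x IQR
#'
#' Computes the lower and upper quartiles of a vector and the clamping
#' fences `Q1 - 3*IQR` and `Q3 + 3*IQR`. Outliers disproportionately
#' inflate skewness and kurtosis (and hence BC), and there is no
#' consensus on deleting them; clamping at a wide 3 x IQR fence tempers
#' them while keeping every sample in the analysis.
#'
#' Quartiles use linear interpolation of order statistics at fractional
#' index `(n - 1) * q` (R's `quantile()` type 7) by default; the dialect
#' is exposed because fence positions at small n can differ across
#' conventions.
#'
#' @param x Numeric vector with at least 4 finite values.
#' @param quartile_type Quantile algorithm passed to
#'   [stats::quantile()]'s `type` (default 7).
#' @return A one-row tibble with columns `q1`, `q3`, `iqr`, `lower`,
#'   `upper`.
#' @examples
#' compute_fences(c(1, 2, 3, 4, 100)) # Q1 2, Q3 4, fences -4 and 10
#' @export
compute_fences <- function(x, quartile_type = 7) {
  x <- x[is.finite(x)]
  if (length(x) < 4) {
    rlang::abort(
      "Fences require at least 4 finite values.",
      class = "bcdscreen_error_too_few_values"
    )
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = quartile_type, names = FALSE)
  iqr <- q[2] - q[1]
  tibble::tibble(
    q1 = q[1], q3 = q[2], iqr = iqr,
    lower = q[1] - 3 * iqr, upper = q[2] + 3 * iqr
  )
}

#' Clamp values at winsorization fences
#'
#' Replaces values above `fences$upper` with the upper fence and values
#' below `fences$lower` with the lower fence. Clamping is total (no
#' value is ever dropped) and idempotent for fixed fences. The identity
#' of clamped samples is retained so that the covariate composition of
#' a second mode can be interrogated later (see [fence_diagnostics()]).
#'
#' @param x Numeric vector.
#' @param fences One-row data frame from [compute_fences()] (or any
#'   data frame with `lower` and `upper` columns). When `NULL`, fences
#'   are computed from `x` itself.
#' @param ids Optional sample identifiers parallel to `x`, recorded for
#'   clamped positions.
#' @inheritParams compute_fences
#' @return The clamped numeric vector, with attributes `n_clamped_low`,
#'   `n_clamped_high`, `clamped_low_ids`, `clamped_high_ids`.
#' @examples
#' f <- compute_fences(c(1, 2, 3, 4, 100))
#' winsorize(c(1, 2, 3, 4, 100), f) # 100 clamped to 10
#' @export
winsorize <- function(x, fences = NULL, ids = NULL, quartile_type = 7) {
  if (is.null(fences)) fences <- compute_fences(x, quartile_type = quartile_type)
  lo <- x < fences$lower & is.finite(x)
  hi <- x > fences$upper & is.finite(x)
  out <- x
  out[lo] <- fences$lower
  out[hi] <- fences$upper
  if (is.null(ids)) ids <- seq_along(x)
  structure(
    out,
    n_clamped_low = sum(lo), n_clamped_high = sum(hi),
    clamped_low_ids = ids[lo], clamped_high_ids = ids[hi]
  )
}

#' Min/max normalization to [0, 1]
#'
#' Scales and shifts a vector to span exactly [0, 1]:
#' `(x - min) / (max - min)`. Used before fold-change computation
#' because simulated or background-corrected expression values can be
#' negative, where a ratio of raw centers is meaningless.
#'
#' @param x Non-constant numeric vector.
#' @return Numeric vector in [0, 1] with the minimum mapped to 0 and
#'   the maximum to 1.
#' @examples
#' minmax_normalize(c(-1, 0, 1)) # 0, 0.5, 1
#' @export
minmax_normalize <- function(x) {
  rng <- range(x, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    rlang::abort(
      "Min/max normalization is undefined for a constant vector.",
      class = "bcdscreen_error_constant_input"
    )
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Exclude samples by covariate level
#'
#' Restricts a phenotype table (and optionally the matching expression
#' table) to samples whose covariate value is not in the excluded set.
#' This is the manoeuvre used to remove strata whose case/control
#' imbalance manufactures spurious second modes (e.g. dropping
#' over-represented brain regions before re-screening).
#'
#' @param pheno Phenotype data frame with a `sample_id` column, a
#'   `status` column (`"case"`/`"control"`) and covariate columns.
#' @param covariate Name of the covariate column to filter on.
#' @param exclude Vector of levels to drop.
#' @param expr Optional expression data frame (first column analyte
#'   ids, remaining columns one per sample) filtered to the retained
#'   samples.
#' @return When `expr` is `NULL`, the filtered phenotype tibble;
#'   otherwise a list with elements `pheno` and `expr`. The retained
#'   case/control counts are attached as attribute `group_counts`.
#' @examples
#' ph <- tibble::tibble(
#'   sample_id = paste0("s", 1:4),
#'   status = c("case", "case", "control", "control"),
#'   region = c(1, 2, 1, 4)
#' )
#' filter_samples(ph, "region", c(2, 4))
#' @export
filter_samples <- function(pheno, covariate, exclude, expr = NULL) {
  if (!covariate %in% names(pheno)) {
    rlang::abort(
      paste0("Covariate `", covariate, "` not found in the phenotype table."),
      class = "bcdscreen_error_unknown_covariate"
    )
  }
  keep <- !(pheno[[covariate]] %in% exclude)
  out <- tibble::as_tibble(pheno)[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    rlang::abort(
      "No samples remain after filtering.",
      class = "bcdscreen_error_empty_result"
    )
  }
  counts <- table(out$status)
  attr(out, "group_counts") <- c(
    cases = unname(counts["case"]), controls = unname(counts["control"])
  )
  if (is.null(expr)) {
    return(out)
  }
  expr <- tibble::as_tibble(expr)
  keep_cols <- c(names(expr)[1], out$sample_id)
  list(pheno = out, expr = expr[, keep_cols])
}
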