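#' Absolute log2 fold change between group centers
#'
#' The classical differential-expression comparator:
#' \eqn{\mathrm{log2FC} = |\log_2(c_{cases} / c_{controls})|} where the
#' centers are group medians (default) or means. Because simulated or
#' background-corrected data can contain negative values, callers are
#' expected to min/max-normalize to [0, 1] first (see
#' [minmax_normalize()]); the quotient is undefined when either center
#' is non-positive, mirroring the well-known instability of fold change
#' near the noise floor.
#'
#' @param cases,controls Numeric vectors of (normalized) values.
#' @param center Central tendency used in the quotient: `"median"`
#'   (default) or `"mean"`.
#' @return A one-row tibble with columns `log2fc` (>= 0), `direction`
#'   (`"up"` when cases > controls, else `"down"`), `center_cases`,
#'   `center_controls`.
#' @examples
#' log2_fold_change(c(0.2, 0.2), c(0.1, 0.1)) # log2fc = 1, up
#' @export
log2_fold_change <- function(cases, controls, center = c("median", "mean")) {
  center <- rlang::arg_match(center)
  fun <- if (center == "median") stats::median else mean
  cc <- fun(cases, na.rm = TRUE)
  ck <- fun(controls, na.rm = TRUE)
  if (!is.finite(cc) || !is.finite(ck) || cc <= 0 || ck <= 0) {
    rlang::abort(
      "Fold change is undefined for non-positive group centers; min/max-normalize first.",
      class = "bcdscreen_error_undefined_fc"
    )
  }
  tibble::tibble(
    log2fc = abs(log2(cc / ck)),
    direction = if (cc > ck) "up" else "down",
    center_cases = cc, center_controls = ck
  )
}

# Raw rank AUC: probability a random case outranks a random control,
# ties counting one half. Midrank sums make this exactly the normalized
# Mann-Whitney U statistic.
rank_auc_raw <- function(cases, controls) {
  n1 <- length(cases)
  n2 <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Area under the ROC curve (folded rank AUC)
#'
#' Computes the area under the receiver operating characteristic curve
#' between cases and controls as the rank (Mann-Whitney) statistic: the
#' proportion of (case, control) pairs in which the case value is
#' larger, with ties contributing one half. The primary statistic `auc`
#' is the folded, orientation-free value `max(A, 1 - A)`, which matches
#' what an in-sample fitted classifier reports: the fit adapts its sign
#' to the data, so even a null marker scores slightly above 0.5.
#'
#' With `method = "logistic"` a univariate logistic regression is fitted
#' and the folded rank AUC of its fitted probabilities is returned. The
#' fitted probabilities are monotone in the single covariate, so this
#' path agrees with the rank path except in the degenerate sign cases;
#' it exists for parity with ROC tooling and is not the default.
#'
#' @param cases,controls Non-empty numeric vectors.
#' @param method `"rank"` (default, deterministic and tie-safe) or
#'   `"logistic"`.
#' @return A one-row tibble with columns `auc` (folded, in [0.5, 1]),
#'   `auc_raw` (in [0, 1], oriented cases-high), `n_cases`,
#'   `n_controls`.
#' @examples
#' rank_auc(c(2, 3), c(0, 1)) # perfect separation, auc = 1
#' rank_auc(c(0, 2), c(1, 3)) # auc_raw 0.25, folded 0.75
#' @export
rank_auc <- function(cases, controls, method = c("rank", "logistic")) {
  method <- rlang::arg_match(method)
  cases <- cases[is.finite(cases)]
  controls <- controls[is.finite(controls)]
  if (length(cases) == 0L || length(controls) == 0L) {
    rlang::abort(
      "Both groups must contain at least one finite value.",
      class = "bcdscreen_error_too_few_values"
    )
  }
  a <- rank_auc_raw(cases, controls)
  if (method == "logistic") {
    x <- c(cases, controls)
    y <- rep(c(1L, 0L), c(length(cases), length(controls)))
    fit <- stats::glm(y ~ x, family = stats::binomial())
    p <- stats::fitted(fit)
    a <- rank_auc_raw(p[y == 1L], p[y == 0L])
  }
  tibble::tibble(
    auc = max(a, 1 - a), auc_raw = a,
    n_cases = length(cases), n_controls = length(controls)
  )
}
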