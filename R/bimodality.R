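#' Central sample moments, skewness and excess kurtosis
#'
#' Computes the first four central sample moments of a numeric vector
#' (averaged over `n`, i.e. the plain moment estimators) together with
#' skewness and excess kurtosis. These are the ingredients of Sarle's
#' bimodality coefficient.
#'
#' Moments are computed after subtracting the sample mean, so large
#' absolute intensities (common in expression data) do not cause
#' catastrophic cancellation. With `type = "moment"` (the default) the
#' estimators are \eqn{g_1 = m_3 / m_2^{3/2}} and
#' \eqn{g_2 = m_4 / m_2^2 - 3}; with `type = "bias_corrected"` the usual
#' small-sample corrected versions \eqn{G_1, G_2} are returned instead.
#' For a constant vector (\eqn{m_2 = 0}) skewness and kurtosis are
#' undefined and reported as `NA`.
#'
#' @param x Numeric vector with at least 2 finite values. `NA`s are
#'   dropped (their count is recorded in the result).
#' @param type Skewness/kurtosis estimator convention: `"moment"` for the
#'   plain moment estimators g1/g2, `"bias_corrected"` for G1/G2.
#'
#' @return A one-row tibble with columns `n`, `n_dropped`, `mean`, `m2`,
#'   `m3`, `m4`, `skewness`, `kurtosis` (excess).
#'
#' @examples
#' sample_moments(c(0, 0, 1, 1)) # skewness 0, excess kurtosis -2
#' @export
sample_moments <- function(x, type = c("moment", "bias_corrected")) {
  type <- rlang::arg_match(type)
  x0 <- as.numeric(x)
  x <- x0[is.finite(x0)]
  n <- length(x)
  if (n < 2) {
    rlang::abort(
      "`x` must contain at least 2 finite values.",
      class = "bcdscreen_error_too_few_values"
    )
  }
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  if (m2 > 0) {
    s <- m3 / m2^1.5
    k <- m4 / m2^2 - 3
    if (type == "bias_corrected" && n > 3) {
      s <- s * sqrt(n * (n - 1)) / (n - 2)
      k <- ((n + 1) * k + 6) * (n - 1) / ((n - 2) * (n - 3))
    }
  } else {
    s <- NA_real_
    k <- NA_real_
  }
  tibble::tibble(
    n = n, n_dropped = length(x0) - n, mean = mu,
    m2 = m2, m3 = m3, m4 = m4, skewness = s, kurtosis = k
  )
}

#' Sarle's bimodality coefficient from moment summaries
#'
#' Evaluates \deqn{BC = \frac{s^2 + 1}{k + 3\,\frac{(n-1)^2}{(n-2)(n-3)}}}
#' where `s` is skewness, `k` excess kurtosis and the third term is the
#' finite-sample correction. In the large-`n` limit the correction tends
#' to 1 and the uniform distribution (s = 0, k = -6/5) gives BC = 5/9.
#'
#' This is the formula layer shared by [bimodality_coefficient()]; it is
#' exported so that analytic limits (e.g. the asymptotic uniform value)
#' can be evaluated directly.
#'
#' @param skewness,kurtosis Skewness and excess kurtosis.
#' @param correction Finite-sample correction factor
#'   \eqn{(n-1)^2 / ((n-2)(n-3))}; use 1 for the asymptotic limit.
#' @return The bimodality coefficient, a value in (0, 1).
#' @examples
#' bc_from_moments(0, -6 / 5, 1) # uniform limit, 5/9
#' @export
bc_from_moments <- function(skewness, kurtosis, correction) {
  (skewness^2 + 1) / (kurtosis + 3 * correction)
}

#' Sarle's bimodality coefficient (BC)
#'
#' Computes the bimodality coefficient of a numeric vector. BC lies in
#' (0, 1); higher values indicate greater bimodality (or skew). The
#' uniform distribution has the asymptotic value 5/9, a normal
#' distribution about 1/3.
#'
#' Because the finite-sample correction \eqn{(n-1)^2/((n-2)(n-3))} is
#' undefined below n = 4, and skewness/kurtosis are undefined for a
#' constant vector, both conditions raise classed errors rather than
#' returning a sentinel, so matrix-wide screens can count and log
#' skipped analytes.
#'
#' @inheritParams sample_moments
#' @return A one-row tibble with columns `bc`, `n`, `correction`,
#'   `skewness`, `kurtosis`.
#' @examples
#' bimodality_coefficient(c(0, 0, 1, 1)) # 2/23
#' bimodality_coefficient(rnorm(1000))   # about 1/3
#' @export
bimodality_coefficient <- function(x, type = c("moment", "bias_corrected")) {
  m <- sample_moments(x, type = type)
  if (m$n < 4) {
    rlang::abort(
      "BC requires at least 4 finite values (finite-sample correction undefined below n = 4).",
      class = "bcdscreen_error_too_few_values"
    )
  }
  if (m$m2 == 0) {
    rlang::abort(
      "BC is undefined for a constant vector.",
      class = "bcdscreen_error_constant_input"
    )
  }
  corr <- (m$n - 1)^2 / ((m$n - 2) * (m$n - 3))
  tibble::tibble(
    bc = bc_from_moments(m$skewness, m$kurtosis, corr),
    n = m$n, correction = corr,
    skewness = m$skewness, kurtosis = m$kurtosis
  )
}

#' Bimodality Coefficient Difference (BCD)
#'
#' The subtype-detection statistic: the absolute difference between the
#' bimodality coefficients of the diseased cases and of the normal
#' controls, \eqn{BCD = |BC_{cases} - BC_{controls}|}. A biomarker that
#' marks a subset of the cases produces a second mode (or skew) in the
#' case distribution only, pushing BCD up; the absolute value protects
#' against the controls being the more bimodal group.
#'
#' BCD lies in [0, 1). It is invariant to affine rescaling of the
#' values, so it does not require normalization.
#'
#' @param cases,controls Numeric vectors of analyte values for the two
#'   groups; each must satisfy the [bimodality_coefficient()]
#'   preconditions (n >= 4, non-constant).
#' @inheritParams sample_moments
#' @return A one-row tibble with columns `bcd`, `bc_cases`,
#'   `bc_controls`, `n_cases`, `n_controls`.
#' @examples
#' x <- rnorm(500, 0.03, 0.04)
#' y <- c(rnorm(250, 0.03, 0.04), rnorm(250, 0.40, 0.16))
#' bcd(y, x)
#' @export
bcd <- function(cases, controls, type = c("moment", "bias_corrected")) {
  bc_case <- tryCatch(
    bimodality_coefficient(cases, type = type),
    error = function(e) rlang::abort("BC failed for the cases group.", parent = e)
  )
  bc_ctrl <- tryCatch(
    bimodality_coefficient(controls, type = type),
    error = function(e) rlang::abort("BC failed for the controls group.", parent = e)
  )
  tibble::tibble(
    bcd = abs(bc_case$bc - bc_ctrl$bc),
    bc_cases = bc_case$bc, bc_controls = bc_ctrl$bc,
    n_cases = bc_case$n, n_controls = bc_ctrl$n
  )
}
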