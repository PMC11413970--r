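# Fast scalar paths used inside the trial loop; the exported tibble
# wrappers in bimodality.R / reference_metrics.R share the same math.
.bc <- function(x) {
  n <- length(x)
  d <- x - mean(x)
  m2 <- mean(d^2)
  s <- mean(d^3) / m2^1.5
  k <- mean(d^4) / m2^2 - 3
  (s^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Simulation scenario specification
#'
#' Describes one subtype-fraction scenario of the two-component
#' Gaussian-mixture benchmark. Per trial, `n_cases` case values and
#' `n_controls` control values are drawn; a fraction
#' `subtype_fraction` of the cases (rounded to a count) comes from the
#' subtype distribution N2, and every other value - the remaining
#' cases and all controls - from the background distribution N1.
#'
#' The default parameters N1 ~ (mean 0.03, SD 0.04) and
#' N2 ~ (mean 0.40, SD 0.16) describe a nearly ideal subtype marker:
#' the modes are separated by about nine background SDs, so any failure
#' to detect the subtype is attributable to the metric, not the signal.
#'
#' @param subtype_fraction Proportion of cases drawn from N2, in
#'   [0, 1].
#' @param mu1,sigma1 Mean and SD of the background distribution N1.
#' @param mu2,sigma2 Mean and SD of the subtype distribution N2.
#' @param n_cases,n_controls Samples per group per trial.
#' @param n_trials Number of trials.
#' @param seed Base seed; each trial uses a substream derived from
#'   `(seed, trial)` so trials are reproducible independently.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(subtype_fraction,
                          mu1 = 0.03, sigma1 = 0.04,
                          mu2 = 0.40, sigma2 = 0.16,
                          n_cases = 1000, n_controls = 1000,
                          n_trials = 1000, seed = 1L) {
  stopifnot(
    subtype_fraction >= 0, subtype_fraction <= 1,
    sigma1 > 0, sigma2 > 0, n_cases >= 4, n_controls >= 4, n_trials >= 1
  )
  structure(
    list(
      subtype_fraction = subtype_fraction,
      mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_trials = as.integer(n_trials), seed = as.integer(seed)
    ),
    class = "scenario_spec"
  )
}

.trial_seed <- function(seed, trial_index) {
  as.integer((as.numeric(seed) + (trial_index - 1) * 2654435761) %% 2147483647)
}

#' Draw one simulation trial
#'
#' Generates the case and control values of a single trial of a
#' [scenario_spec()]. Exactly `round(subtype_fraction * n_cases)` case
#' values come from N2; the remaining cases and all controls come from
#' N1. The draw is reproducible from `(spec$seed, trial_index)` alone.
#'
#' @param spec A [scenario_spec()].
#' @param trial_index Trial number, 1-based.
#' @return A list with numeric vectors `cases` (subtype draws first)
#'   and `controls`, and the integer `n_subtype`.
#' @export
draw_trial <- function(spec, trial_index = 1L) {
  set.seed(.trial_seed(spec$seed, trial_index))
  n_sub <- as.integer(round(spec$subtype_fraction * spec$n_cases))
  cases <- c(
    stats::rnorm(n_sub, spec$mu2, spec$sigma2),
    stats::rnorm(spec$n_cases - n_sub, spec$mu1, spec$sigma1)
  )
  controls <- stats::rnorm(spec$n_controls, spec$mu1, spec$sigma1)
  list(cases = cases, controls = controls, n_subtype = n_sub)
}

# Winsorize a case/control pair under the configured scope and return
# the clamped vectors.
.winsorize_groups <- function(cases, controls,
                              scope = c("pooled", "per-group", "off"),
                              quartile_type = 7) {
  scope <- match.arg(scope)
  if (scope == "off") {
    return(list(cases = cases, controls = controls))
  }
  if (scope == "pooled") {
    f <- compute_fences(c(cases, controls), quartile_type = quartile_type)
    list(
      cases = as.numeric(winsorize(cases, f)),
      controls = as.numeric(winsorize(controls, f))
    )
  } else {
    list(
      cases = as.numeric(winsorize(cases, compute_fences(cases, quartile_type = quartile_type))),
      controls = as.numeric(winsorize(controls, compute_fences(controls, quartile_type = quartile_type)))
    )
  }
}

# One trial's metric triple on already-drawn values.
.score_trial <- function(cases, controls, winsorize_scope, fc_center, quartile_type) {
  w <- .winsorize_groups(cases, controls, winsorize_scope, quartile_type)
  bcd_val <- abs(.bc(w$cases) - .bc(w$controls))
  a <- rank_auc_raw(w$cases, w$controls)
  pool <- c(w$cases, w$controls)
  rng <- range(pool)
  nc <- (w$cases - rng[1]) / (rng[2] - rng[1])
  nk <- (w$controls - rng[1]) / (rng[2] - rng[1])
  cfun <- if (fc_center == "median") stats::median else mean
  cc <- cfun(nc)
  ck <- cfun(nk)
  if (cc <= 0 || ck <= 0) {
    rlang::abort("undefined fold change", class = "bcdscreen_error_undefined_fc")
  }
  c(log2fc = abs(log2(cc / ck)), auc = max(a, 1 - a), auc_raw = a, bcd = bcd_val)
}

#' Run all trials of one scenario
#'
#' For each trial: draw the mixture, winsorize (pooled fences by
#' default), then score the three metrics - BCD on the winsorized
#' groups, folded rank AUC, and median-based absolute log2 fold change
#' on min/max-normalized winsorized values. Trials whose metrics are
#' undefined (e.g. a non-positive fold-change center) are skipped and
#' counted.
#'
#' @param spec A [scenario_spec()].
#' @param winsorize_scope `"pooled"` (fences from cases and controls
#'   jointly, the default), `"per-group"`, or `"off"`.
#' @param fc_center Central tendency for fold change, `"median"`
#'   (default) or `"mean"`.
#' @param quartile_type Quantile algorithm for the fences.
#' @return A tibble with one row per completed trial: columns
#'   `subtype_fraction`, `trial`, `log2fc`, `auc`, `auc_raw`, `bcd`.
#'   The number of skipped trials is attached as attribute
#'   `n_skipped`.
#' @export
run_scenario <- function(spec,
                         winsorize_scope = c("pooled", "per-group", "off"),
                         fc_center = c("median", "mean"),
                         quartile_type = 7) {
  winsorize_scope <- rlang::arg_match(winsorize_scope)
  fc_center <- rlang::arg_match(fc_center)
  out <- matrix(NA_real_, nrow = spec$n_trials, ncol = 4)
  skipped <- 0L
  for (i in seq_len(spec$n_trials)) {
    tr <- draw_trial(spec, i)
    res <- tryCatch(
      .score_trial(tr$cases, tr$controls, winsorize_scope, fc_center, quartile_type),
      error = function(e) NULL
    )
    if (is.null(res)) skipped <- skipped + 1L else out[i, ] <- res
  }
  done <- !is.na(out[, 1])
  res <- tibble::tibble(
    subtype_fraction = spec$subtype_fraction,
    trial = which(done),
    log2fc = out[done, 1], auc = out[done, 2],
    auc_raw = out[done, 3], bcd = out[done, 4]
  )
  attr(res, "n_skipped") <- skipped
  res
}

#' Run the multi-scenario simulation benchmark
#'
#' Runs [run_scenario()] over a set of subtype fractions (default: the
#' seven-scenario design 0, 5, 10, 20, 30, 40, 50%) and binds the
#' per-trial metric triples into one tibble of class `bcd_simulation`.
#' Summarize with [summarize_trials()] (or `glance()`), tidy with
#' `tidy()`, plot with [autoplot()][autoplot.bcd_simulation].
#'
#' @param fractions Numeric vector of subtype fractions.
#' @param seed Base seed; each scenario gets a derived sub-seed so the
#'   whole benchmark is reproducible from one integer.
#' @inheritParams scenario_spec
#' @inheritParams run_scenario
#' @return A `bcd_simulation` tibble: one row per (scenario, trial)
#'   with columns `subtype_fraction`, `trial`, `log2fc`, `auc`,
#'   `auc_raw`, `bcd`.
#' @examples
#' sim <- simulate_scenarios(c(0, 0.5), n_trials = 20, seed = 7)
#' summarize_trials(sim)
#' @export
simulate_scenarios <- function(fractions = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                               n_trials = 1000,
                               n_cases = 1000, n_controls = 1000,
                               mu1 = 0.03, sigma1 = 0.04,
                               mu2 = 0.40, sigma2 = 0.16,
                               seed = 1L,
                               winsorize_scope = c("pooled", "per-group", "off"),
                               fc_center = c("median", "mean"),
                               quartile_type = 7) {
  winsorize_scope <- rlang::arg_match(winsorize_scope)
  fc_center <- rlang::arg_match(fc_center)
  res <- purrr::map(seq_along(fractions), function(k) {
    spec <- scenario_spec(
      fractions[k],
      mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
      n_cases = n_cases, n_controls = n_controls, n_trials = n_trials,
      seed = .trial_seed(seed, 1000003 * k)
    )
    run_scenario(spec, winsorize_scope, fc_center, quartile_type)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("bcd_simulation", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "winsorize_scope") <- winsorize_scope
  out
}

#' Summarize simulation trials as median [min, max] per metric
#'
#' Collapses a per-trial metric table into the benchmark summary: for
#' each subtype fraction and each metric, the median, minimum and
#' maximum across trials.
#'
#' @param trials A `bcd_simulation` tibble (or any data frame with
#'   columns `subtype_fraction`, `log2fc`, `auc`, `bcd`).
#' @return A tibble with columns `subtype_fraction`, `metric`,
#'   `median`, `min`, `max`, one row per (scenario, metric).
#' @export
summarize_trials <- function(trials) {
  if (nrow(trials) == 0) {
    rlang::abort("No completed trials to summarize.",
      class = "bcdscreen_error_empty_result"
    )
  }
  trials |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c("log2fc", "auc", "bcd")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$subtype_fraction, .data$metric) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy per-trial simulation results
#'
#' Returns the per-trial metrics in long format: one row per
#' (scenario, trial, metric).
#'
#' @param x A `bcd_simulation` object.
#' @param ... Unused.
#' @return A tibble with columns `subtype_fraction`, `trial`, `metric`,
#'   `value`.
#' @method tidy bcd_simulation
#' @export
tidy.bcd_simulation <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(
      cols = c("log2fc", "auc", "auc_raw", "bcd"),
      names_to = "metric", values_to = "value"
    )
}

#' One-row-per-scenario summary of a simulation
#'
#' The wide benchmark table: per subtype fraction, the median of each
#' metric with its min/max bracket.
#'
#' @param x A `bcd_simulation` object.
#' @param ... Unused.
#' @return A tibble with one row per scenario and columns
#'   `subtype_fraction`, `n_trials`, then `<metric>_median`,
#'   `<metric>_min`, `<metric>_max` for log2fc, auc and bcd.
#' @method glance bcd_simulation
#' @export
glance.bcd_simulation <- function(x, ...) {
  n <- x |>
    tibble::as_tibble() |>
    dplyr::count(.data$subtype_fraction, name = "n_trials")
  summarize_trials(x) |>
    tidyr::pivot_wider(
      names_from = "metric",
      values_from = c("median", "min", "max"),
      names_glue = "{metric}_{.value}"
    ) |>
    dplyr::left_join(n, by = "subtype_fraction") |>
    dplyr::relocate("n_trials", .after = "subtype_fraction")
}
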