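test_that("trial draws respect the mixture composition and the seed", {
  spec <- scenario_spec(0.5, n_trials = 10, seed = 4)
  tr <- draw_trial(spec, 1)
  expect_equal(tr$n_subtype, 500)
  expect_length(tr$cases, 1000)
  expect_length(tr$controls, 1000)
  # subtype draws come first; CLT bound on their mean
  expect_lt(abs(mean(tr$cases[1:500]) - 0.40), 3 * 0.16 / sqrt(500))
  # identical (spec, trial) reproduces bit-identical values
  tr2 <- draw_trial(spec, 1)
  expect_identical(tr$cases, tr2$cases)
  expect_false(identical(draw_trial(spec, 2)$cases, tr$cases))

  null_spec <- scenario_spec(0, n_trials = 1, seed = 4)
  tr0 <- draw_trial(null_spec, 1)
  expect_equal(tr0$n_subtype, 0)
  expect_lt(abs(mean(c(tr0$cases, tr0$controls)) - 0.03),
            3 * 0.04 / sqrt(2000))
})

test_that("scenario runs are deterministic given the seed", {
  s1 <- simulate_scenarios(c(0, 0.3), n_trials = 25, seed = 12)
  s2 <- simulate_scenarios(c(0, 0.3), n_trials = 25, seed = 12)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  s3 <- simulate_scenarios(c(0, 0.3), n_trials = 25, seed = 13)
  expect_false(identical(s1$bcd, s3$bcd))
})

test_that("summaries collapse trials to median/min/max", {
  one <- tibble::tibble(subtype_fraction = 0.1, log2fc = 0.5, auc = 0.6,
                        bcd = 0.2)
  s <- summarize_trials(one)
  expect_true(all(s$median == s$min & s$median == s$max))
  three <- tibble::tibble(
    subtype_fraction = 0.1,
    log2fc = c(1, 2, 3), auc = c(1, 2, 3), bcd = c(1, 2, 3)
  )
  s3 <- summarize_trials(three)
  expect_true(all(s3$median == 2 & s3$min == 1 & s3$max == 3))
  expect_true(all(s3$min <= s3$median & s3$median <= s3$max))
})

test_that("median raw AUC tracks the closed-form mixture value", {
  # for a subtype fraction p the expected raw AUC is
  # (1 - p) * 0.5 + p * P(N2 > N1) with
  # P(N2 > N1) = pnorm((0.40 - 0.03) / sqrt(0.04^2 + 0.16^2))
  p_win <- pnorm(0.37 / sqrt(0.04^2 + 0.16^2))
  for (p in c(0.1, 0.3, 0.5)) {
    sim <- run_scenario(scenario_spec(p, n_trials = 150, seed = 23))
    expect_equal(median(sim$auc_raw), 0.5 + p * (p_win - 0.5),
      tolerance = 0.005 / (0.5 + p * (p_win - 0.5))
    )
  }
})

test_that("median BCD rises with subtype fraction then dips at 50%", {
  sim <- simulate_scenarios(n_trials = 150, seed = 29)
  med <- summarize_trials(sim) |>
    dplyr::filter(metric == "bcd") |>
    dplyr::arrange(subtype_fraction)
  expect_true(all(diff(med$median[1:6]) > 0)) # 0 -> 40% strictly up
  expect_gt(med$median[6], med$median[7]) # 40% beats 50%
})

test_that("per-group and off winsorization scopes are honoured", {
  spec <- scenario_spec(0.3, n_trials = 10, seed = 31)
  pooled <- run_scenario(spec, winsorize_scope = "pooled")
  off <- run_scenario(spec, winsorize_scope = "off")
  per <- run_scenario(spec, winsorize_scope = "per-group")
  # identical draws, different clamping: BCD must differ across scopes
  expect_false(isTRUE(all.equal(pooled$bcd, off$bcd)))
  expect_false(isTRUE(all.equal(pooled$bcd, per$bcd)))
  # AUC at identical draws is unchanged by any clamping that leaves
  # the case/control order relations intact within fences
  expect_equal(pooled$auc, off$auc, tolerance = 1e-3)
})

test_that("tidy and glance return the advertised shapes", {
  sim <- simulate_scenarios(c(0, 0.2), n_trials = 10, seed = 37)
  td <- generics::tidy(sim)
  expect_setequal(unique(td$metric), c("log2fc", "auc", "auc_raw", "bcd"))
  expect_equal(nrow(td), 2 * 10 * 4)
  gl <- generics::glance(sim)
  expect_equal(nrow(gl), 2)
  expect_true(all(c("bcd_median", "auc_min", "log2fc_max", "n_trials")
                  %in% names(gl)))
  expect_s3_class(ggplot2::autoplot(sim), "ggplot")
})
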