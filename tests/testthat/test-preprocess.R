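test_that("fences interpolate quartiles and sit at 3 x IQR", {
  f <- compute_fences(c(1, 2, 3, 4, 100))
  expect_equal(f$q1, 2)
  expect_equal(f$q3, 4)
  expect_equal(f$iqr, 2)
  expect_equal(f$lower, -4)
  expect_equal(f$upper, 10)
  expect_error(compute_fences(1:3), class = "bcdscreen_error_too_few_values")
  # constant vector: zero IQR, both fences at the constant
  fc <- compute_fences(rep(7, 10))
  expect_equal(fc$lower, 7)
  expect_equal(fc$upper, 7)
  # symmetric data give symmetric fences
  fs <- compute_fences(rep(c(-1, 0, 1), 10))
  expect_equal(fs$lower, -fs$upper)
})

test_that("winsorize clamps at fences and records identities", {
  f <- compute_fences(c(1, 2, 3, 4, 100))
  w <- winsorize(c(1, 2, 3, 4, 100), f, ids = letters[1:5])
  expect_equal(as.numeric(w), c(1, 2, 3, 4, 10))
  expect_equal(attr(w, "n_clamped_high"), 1L)
  expect_equal(attr(w, "n_clamped_low"), 0L)
  expect_equal(attr(w, "clamped_high_ids"), "e")
  # in-range input is untouched
  w2 <- winsorize(c(2, 3, 4), f)
  expect_equal(as.numeric(w2), c(2, 3, 4))
  expect_equal(attr(w2, "n_clamped_high") + attr(w2, "n_clamped_low"), 0L)
})

test_that("winsorization is idempotent and weakly order-preserving", {
  set.seed(17)
  for (i in 1:25) {
    x <- rt(50, df = 2) # heavy tails guarantee some clamping
    f <- compute_fences(x)
    w1 <- as.numeric(winsorize(x, f))
    expect_equal(as.numeric(winsorize(w1, f)), w1)
    ord <- order(x)
    expect_true(all(diff(w1[ord]) >= 0))
    expect_true(all(w1 >= f$lower & w1 <= f$upper))
  }
})

test_that("min/max normalization spans [0, 1] and preserves FC structure", {
  expect_equal(minmax_normalize(c(-1, 0, 1)), c(0, 0.5, 1))
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(30, sd = i)
    z <- minmax_normalize(x)
    expect_equal(min(z), 0)
    expect_equal(max(z), 1)
    # the ratio of normalized medians depends only on the minimum,
    # not the maximum: inflating the max leaves it unchanged
    a <- z[1:15]
    b <- z[16:30]
    x2 <- c(x, max(x) + 10)
    z2 <- minmax_normalize(x2)[1:30]
    r1 <- (median(a)) / (median(b))
    r2 <- (median(z2[1:15])) / (median(z2[16:30]))
    expect_equal(r1, r2, tolerance = 1e-12)
  }
  expect_error(minmax_normalize(rep(2, 5)),
    class = "bcdscreen_error_constant_input"
  )
})

test_that("sample filtering drops excluded covariate levels", {
  ph <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    status = c("case", "case", "control", "control"),
    region = c(1, 1, 2, 4)
  )
  out <- filter_samples(ph, "region", c(2, 4))
  expect_equal(nrow(out), 2)
  expect_identical(filter_samples(ph, "region", integer(0))$sample_id,
                   ph$sample_id)
  expect_error(filter_samples(ph, "brain", 1),
    class = "bcdscreen_error_unknown_covariate"
  )
  expect_error(filter_samples(ph, "region", 1:4),
    class = "bcdscreen_error_empty_result"
  )
})

test_that("region exclusion reproduces the cohort arithmetic of the study design", {
  # synthetic phenotype table shaped like the cortex cohort: 176 cases
  # and 187 controls, of which 39 cases and 12 controls sit in the
  # excluded regions 2 and 4
  ph <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:363),
    status = rep(c("case", "control"), c(176, 187)),
    region = c(
      rep(c(1, 3, 2, 4), c(100, 37, 17, 22)),
      rep(c(1, 3, 2, 4), c(120, 55, 3, 9))
    )
  )
  out <- filter_samples(ph, "region", c(2, 4))
  counts <- attr(out, "group_counts")
  expect_equal(unname(counts["cases"]), 137)
  expect_equal(unname(counts["controls"]), 175)
})

test_that("filtering also subsets the expression table columns", {
  fix <- generate_fixture(n_analytes = 5, n_cases = 10, n_controls = 10,
                          seed = 2)
  lev <- fix$pheno$region[1]
  flt <- filter_samples(fix$pheno, "region", lev, expr = fix$expr)
  expect_equal(ncol(flt$expr) - 1, nrow(flt$pheno))
  expect_setequal(names(flt$expr)[-1], flt$pheno$sample_id)
})
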