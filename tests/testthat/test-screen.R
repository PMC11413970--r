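make_screen_fixture <- function(seed = 101, ...) {
  generate_fixture(
    n_analytes = 20, n_cases = 60, n_controls = 60,
    subtype_analytes = data.frame(analyte = 1, fraction = 0.3),
    confound_analytes = 2, seed = seed, ...
  )
}

test_that("subtype-structured analytes outscore noise analytes", {
  fix <- make_screen_fixture()
  sc <- score_analytes(fix$expr, fix$pheno)
  expect_s3_class(sc, "bcd_scores")
  planted <- sc$bcd[sc$analyte_id == "subtype_0001"]
  nulls <- sc$bcd[startsWith(sc$analyte_id, "null")]
  expect_true(all(planted > nulls))
  expect_equal(sc$rank_bcd[sc$analyte_id == "subtype_0001"], 1L)
  # ranks are permutations of 1..n per metric
  for (col in c("rank_bcd", "rank_log2fc", "rank_auc")) {
    expect_setequal(sc[[col]], seq_len(nrow(sc)))
  }
})

test_that("constant and under-sampled analytes are skipped with reasons", {
  fix <- make_screen_fixture()
  fix$expr[3, -1] <- as.list(rep(5, ncol(fix$expr) - 1))
  fix$expr[4, -1] <- as.list(rep(NA_real_, ncol(fix$expr) - 1))
  sc <- score_analytes(fix$expr, fix$pheno)
  skipped <- attr(sc, "skipped")
  expect_setequal(skipped$analyte_id, fix$expr$analyte_id[3:4])
  expect_match(skipped$reason[skipped$analyte_id == fix$expr$analyte_id[3]],
               "constant")
  expect_match(skipped$reason[skipped$analyte_id == fix$expr$analyte_id[4]],
               "too few")
  expect_equal(nrow(sc), 18)
})

test_that("scores are deterministic and row-order independent", {
  fix <- make_screen_fixture()
  sc1 <- score_analytes(fix$expr, fix$pheno)
  shuffled <- fix$expr[rev(seq_len(nrow(fix$expr))), ]
  sc2 <- score_analytes(shuffled, fix$pheno)
  j <- match(sc1$analyte_id, sc2$analyte_id)
  expect_equal(sc1$bcd, sc2$bcd[j])
  expect_equal(sc1$auc, sc2$auc[j])
  expect_equal(sc1$log2fc, sc2$log2fc[j])
})

test_that("covariate filtering before scoring equals scoring the subset", {
  fix <- make_screen_fixture()
  flt <- filter_samples(fix$pheno, "region", c(2, 4), expr = fix$expr)
  sc_filtered <- score_analytes(flt$expr, flt$pheno)
  keep <- fix$pheno$sample_id[!(fix$pheno$region %in% c(2, 4))]
  manual <- fix$expr[, c("analyte_id", keep)]
  sc_manual <- score_analytes(manual, fix$pheno[fix$pheno$sample_id %in% keep, ])
  expect_equal(tibble::as_tibble(sc_filtered), tibble::as_tibble(sc_manual))
})

test_that("top-fraction extraction uses ceiling counts and id tie-breaks", {
  sc <- tibble::tibble(
    analyte_id = sprintf("a%03d", 1:100),
    bcd = c(rep(0.9, 3), rep(0.1, 97))
  )
  top <- top_fraction(sc, "bcd", 0.05)
  expect_length(top, 5)
  expect_identical(top[1:3], c("a001", "a002", "a003"))
  # boundary ties resolved lexicographically
  expect_identical(top[4:5], c("a004", "a005"))
  expect_length(top_fraction(sc, "bcd", 1), 100)
  expect_equal(ceiling(0.05 * 8650), 433)
})

test_that("overlap percentages follow the first-set denominator", {
  ov <- overlap_report(list(
    fc = c("a", "b", "c", "d"), auc = c("a", "b", "x", "y")
  ))
  expect_equal(ov$pct_of_a, c(50, 50))
  same <- overlap_report(list(x = letters[1:4], y = letters[1:4]))
  expect_true(all(same$pct_of_a == 100))
  expect_equal(attr(same, "triple")$pct, 100)
  disj <- overlap_report(list(x = letters[1:4], y = letters[5:8]))
  expect_true(all(disj$pct_of_a == 0))
  expect_equal(attr(disj, "triple")$n_common, 0)
  # invariant to id renaming and set order
  ren <- overlap_report(list(
    auc = c("A", "B", "X", "Y"), fc = c("A", "B", "C", "D")
  ))
  expect_setequal(ren$pct_of_a, c(50, 50))
  expect_error(overlap_report(list(a = character(0), b = "x")),
    class = "bcdscreen_error_empty_result"
  )
})

test_that("fence diagnostics expose a covariate-confounded second mode", {
  fix <- make_screen_fixture()
  rep4 <- fence_diagnostics(fix$expr, fix$pheno, "confound_0002", "region")
  expect_gt(nrow(rep4), 0)
  lev4 <- dplyr::filter(rep4, level == "4")
  expect_true(all(lev4$enriched))
  expect_true(all(lev4$prop_clamped >= 0.9))
  # proportions within each clamped set sum to one
  sums <- dplyr::summarise(
    dplyr::group_by(rep4, group), s = sum(prop_clamped)
  )
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # an analyte with nothing clamped yields an empty report
  clean <- fence_diagnostics(fix$expr, fix$pheno, "null_0005", "region")
  expect_equal(nrow(clean), 0)
})

test_that("permutation p-values rank a planted analyte first and stay in (0, 1]", {
  fix <- make_screen_fixture()
  sc <- score_analytes(fix$expr, fix$pheno)
  sc <- empirical_pvalues(sc, fix$expr, fix$pheno,
    n_permutations = 40, seed = 9
  )
  expect_true(all(sc$p_bcd > 0 & sc$p_bcd <= 1))
  expect_equal(which.min(sc$p_bcd), which(sc$analyte_id == "subtype_0001"))
  # the permutation cutoff attribute is the null 95th percentile
  expect_true(all(is.finite(attr(sc, "cutoffs"))))
  expect_error(
    empirical_pvalues(sc, fix$expr, fix$pheno, n_permutations = 5),
    class = "bcdscreen_error_bad_input"
  )
})

test_that("binned histogram export counts every sample once per group", {
  fix <- make_screen_fixture()
  h <- analyte_histogram(fix$expr, fix$pheno, "subtype_0001", bins = 15)
  counts <- tapply(h$count, h$group, sum)
  expect_equal(unname(counts["case"]), 60)
  expect_equal(unname(counts["control"]), 60)
  expect_s3_class(plot_analyte(fix$expr, fix$pheno, "subtype_0001"), "ggplot")
})
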