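# Align an expression table (first column analyte ids, one column per
# sample) with a phenotype table. Returns the numeric matrix plus the
# case/control split of its columns.
.align_matrix <- function(expr, pheno) {
  expr <- tibble::as_tibble(expr)
  pheno <- tibble::as_tibble(pheno)
  id_col <- names(expr)[1]
  ids <- as.character(expr[[id_col]])
  if (anyDuplicated(ids)) {
    rlang::abort("Analyte ids must be unique.", class = "bcdscreen_error_bad_input")
  }
  sample_cols <- names(expr)[-1]
  missing <- setdiff(sample_cols, pheno$sample_id)
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Samples missing from the phenotype table: ",
             paste(utils::head(missing, 5), collapse = ", ")),
      class = "bcdscreen_error_bad_input"
    )
  }
  status <- pheno$status[match(sample_cols, pheno$sample_id)]
  if (!all(status %in% c("case", "control"))) {
    rlang::abort("`status` must be 'case' or 'control' for every sample.",
      class = "bcdscreen_error_bad_input"
    )
  }
  m <- as.matrix(expr[, -1])
  mode(m) <- "numeric"
  rownames(m) <- ids
  list(
    values = m, analyte_ids = ids, sample_ids = sample_cols,
    is_case = status == "case"
  )
}

# Metric set for one analyte on pre-split, NA-free values.
.score_analyte <- function(case_vals, ctrl_vals, winsorize_scope, fc_center,
                           quartile_type) {
  w <- .winsorize_groups(case_vals, ctrl_vals, winsorize_scope, quartile_type)
  if (stats::var(w$cases) == 0 || stats::var(w$controls) == 0) {
    rlang::abort("constant after winsorization",
      class = "bcdscreen_error_constant_input"
    )
  }
  bc_ca <- .bc(w$cases)
  bc_co <- .bc(w$controls)
  a <- rank_auc_raw(w$cases, w$controls)
  pool <- c(w$cases, w$controls)
  rng <- range(pool)
  cfun <- if (fc_center == "median") stats::median else mean
  cc <- (cfun(w$cases) - rng[1]) / (rng[2] - rng[1])
  ck <- (cfun(w$controls) - rng[1]) / (rng[2] - rng[1])
  lfc <- if (cc > 0 && ck > 0) abs(log2(cc / ck)) else NA_real_
  c(
    bcd = abs(bc_ca - bc_co), bc_cases = bc_ca, bc_controls = bc_co,
    log2fc = lfc, auc = max(a, 1 - a), auc_raw = a
  )
}

#' Score every analyte of an expression matrix
#'
#' Runs the full per-analyte pipeline over a genes-by-samples
#' expression table: pooled 3 x IQR winsorization, then BCD on the
#' winsorized case and control values, folded rank AUC, and
#' median-based absolute log2 fold change on min/max-normalized
#' winsorized values. Analytes with fewer than `min_group_n`
#' non-missing values in either group, or constant after
#' winsorization, are skipped and logged.
#'
#' @param expr Expression data frame: first column analyte ids, one
#'   numeric column per sample (missing values as `NA`).
#' @param pheno Phenotype data frame with columns `sample_id` and
#'   `status` (`"case"`/`"control"`), plus optional covariates.
#' @param winsorize_scope `"pooled"` (default), `"per-group"` or
#'   `"off"`.
#' @param fc_center `"median"` (default) or `"mean"`.
#' @param quartile_type Quantile algorithm for fences.
#' @param min_group_n Minimum non-missing values per group (>= 4).
#' @return A `bcd_scores` tibble, one row per scored analyte:
#'   `analyte_id`, `bcd`, `bc_cases`, `bc_controls`, `log2fc`, `auc`,
#'   `auc_raw`, `n_clamped_cases`, `n_clamped_controls`, and per-metric
#'   descending ranks `rank_bcd`, `rank_log2fc`, `rank_auc`. Skipped
#'   analytes and their reasons are in attribute `skipped`. No
#'   multiple-testing correction is applied anywhere in this pipeline.
#' @examples
#' fix <- generate_fixture(n_analytes = 10, n_cases = 30, n_controls = 30,
#'                         seed = 1)
#' score_analytes(fix$expr, fix$pheno)
#' @export
score_analytes <- function(expr, pheno,
                           winsorize_scope = c("pooled", "per-group", "off"),
                           fc_center = c("median", "mean"),
                           quartile_type = 7, min_group_n = 4) {
  winsorize_scope <- rlang::arg_match(winsorize_scope)
  fc_center <- rlang::arg_match(fc_center)
  stopifnot(min_group_n >= 4)
  al <- .align_matrix(expr, pheno)
  n_an <- length(al$analyte_ids)
  out <- matrix(NA_real_, nrow = n_an, ncol = 8)
  skip_reason <- character(n_an)
  for (i in seq_len(n_an)) {
    ca <- al$values[i, al$is_case]
    co <- al$values[i, !al$is_case]
    ca <- ca[is.finite(ca)]
    co <- co[is.finite(co)]
    if (length(ca) < min_group_n || length(co) < min_group_n) {
      skip_reason[i] <- "too few non-missing values"
      next
    }
    res <- tryCatch(
      {
        w <- .winsorize_groups(ca, co, winsorize_scope, quartile_type)
        s <- .score_analyte(ca, co, winsorize_scope, fc_center, quartile_type)
        c(s, sum(w$cases != ca), sum(w$controls != co))
      },
      bcdscreen_error_constant_input = function(e) {
        skip_reason[i] <<- "constant values"
        NULL
      },
      error = function(e) {
        skip_reason[i] <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(res)) out[i, ] <- res
  }
  ok <- !is.na(out[, 1])
  if (!any(ok)) {
    rlang::abort("Every analyte was skipped; nothing to score.",
      class = "bcdscreen_error_empty_result"
    )
  }
  scores <- tibble::tibble(
    analyte_id = al$analyte_ids[ok],
    bcd = out[ok, 1], bc_cases = out[ok, 2], bc_controls = out[ok, 3],
    log2fc = out[ok, 4], auc = out[ok, 5], auc_raw = out[ok, 6],
    n_clamped_cases = as.integer(out[ok, 7]),
    n_clamped_controls = as.integer(out[ok, 8])
  )
  rank_desc <- function(v) {
    # deterministic permutation of 1..n: ties broken by analyte id
    ord <- order(-v, scores$analyte_id)
    r <- integer(length(v))
    r[ord] <- seq_along(v)
    r
  }
  scores$rank_bcd <- rank_desc(scores$bcd)
  scores$rank_log2fc <- rank_desc(scores$log2fc)
  scores$rank_auc <- rank_desc(scores$auc)
  class(scores) <- c("bcd_scores", class(scores))
  attr(scores, "skipped") <- tibble::tibble(
    analyte_id = al$analyte_ids[!ok], reason = skip_reason[!ok]
  )
  attr(scores, "config") <- list(
    winsorize_scope = winsorize_scope, fc_center = fc_center,
    quartile_type = quartile_type, min_group_n = min_group_n
  )
  scores
}

#' Empirical significance by label permutation
#'
#' Attaches empirical p-values to an analyte score table by permuting
#' the case/control labels. For each permutation the three metrics are
#' recomputed for every analyte; null values are pooled across analytes
#' and permutations, and each observed value gets
#' \eqn{p = (b + 1) / (B_{total} + 1)} where `b` counts null values at
#' least as large. The pooled null's 95th percentile per metric is the
#' empirical cutoff for p <= 0.05 and is attached as attribute
#' `cutoffs`.
#'
#' Pooled winsorization fences ignore the labels, so the winsorized
#' matrix is computed once and only the group split changes per
#' permutation. No multiple-testing correction is applied, so treat
#' these p-values as screening scores, not confirmatory inference.
#'
#' @param scores A `bcd_scores` tibble from [score_analytes()].
#' @param expr,pheno The tables the scores were computed from.
#' @param n_permutations Number of label permutations (>= 19 so that
#'   p = 0.05 is attainable).
#' @param seed Seed for the permutation stream.
#' @return `scores` with added columns `p_bcd`, `p_log2fc`, `p_auc`;
#'   attribute `cutoffs` holds the per-metric null 95th percentiles.
#' @export
empirical_pvalues <- function(scores, expr, pheno, n_permutations = 100,
                              seed = 1L) {
  if (n_permutations < 19) {
    rlang::abort("Need at least 19 permutations for p <= 0.05 resolution.",
      class = "bcdscreen_error_bad_input"
    )
  }
  cfg <- attr(scores, "config")
  al <- .align_matrix(expr, pheno)
  keep <- match(scores$analyte_id, al$analyte_ids)
  vals <- al$values[keep, , drop = FALSE]
  n_samp <- ncol(vals)
  n1 <- sum(al$is_case)
  if (choose(n_samp, n1) < 20) {
    rlang::abort("Too few samples for a meaningful permutation null.",
      class = "bcdscreen_error_bad_input"
    )
  }
  # Pre-winsorize rows once: pooled fences are label-free.
  if (cfg$winsorize_scope == "pooled") {
    vals <- t(apply(vals, 1, function(v) {
      fin <- is.finite(v)
      v[fin] <- as.numeric(winsorize(v[fin], quartile_type = cfg$quartile_type))
      v
    }))
  }
  n_an <- nrow(vals)
  set.seed(as.integer(seed) %% 2147483647L)
  null_bcd <- null_fc <- null_auc <- matrix(NA_real_, n_an, n_permutations)
  for (b in seq_len(n_permutations)) {
    perm_case <- seq_len(n_samp) %in% sample.int(n_samp, n1)
    for (i in seq_len(n_an)) {
      ca <- vals[i, perm_case]
      co <- vals[i, !perm_case]
      ca <- ca[is.finite(ca)]
      co <- co[is.finite(co)]
      res <- tryCatch(
        .score_analyte(
          ca, co,
          # rows already winsorized under pooled scope
          if (cfg$winsorize_scope == "pooled") "off" else cfg$winsorize_scope,
          cfg$fc_center, cfg$quartile_type
        ),
        error = function(e) NULL
      )
      if (!is.null(res)) {
        null_bcd[i, b] <- res["bcd"]
        null_fc[i, b] <- res["log2fc"]
        null_auc[i, b] <- res["auc"]
      }
    }
  }
  emp_p <- function(obs, null_pool) {
    null_pool <- null_pool[is.finite(null_pool)]
    b_total <- length(null_pool)
    vapply(obs, function(o) {
      if (!is.finite(o)) return(NA_real_)
      (sum(null_pool >= o) + 1) / (b_total + 1)
    }, numeric(1))
  }
  scores$p_bcd <- emp_p(scores$bcd, null_bcd)
  scores$p_log2fc <- emp_p(scores$log2fc, null_fc)
  scores$p_auc <- emp_p(scores$auc, null_auc)
  attr(scores, "cutoffs") <- c(
    bcd = stats::quantile(null_bcd[is.finite(null_bcd)], 0.95, names = FALSE),
    log2fc = stats::quantile(null_fc[is.finite(null_fc)], 0.95, names = FALSE),
    auc = stats::quantile(null_auc[is.finite(null_auc)], 0.95, names = FALSE)
  )
  attr(scores, "n_permutations") <- as.integer(n_permutations)
  attr(scores, "seed") <- as.integer(seed)
  scores
}

#' Extract the top fraction of analytes by one metric
#'
#' Returns the `ceiling(fraction * n)` analyte ids with the largest
#' values of the chosen metric. Ties at the boundary are broken by
#' analyte id (lexicographic), so the extraction is deterministic.
#'
#' @param scores A `bcd_scores` tibble.
#' @param metric One of `"bcd"`, `"log2fc"`, `"auc"`.
#' @param fraction Fraction of analytes to keep, in (0, 1]. The
#'   conventional screening choice is the top 5%.
#' @return Character vector of analyte ids, in decreasing metric order.
#' @export
top_fraction <- function(scores, metric = c("bcd", "log2fc", "auc"),
                         fraction = 0.05) {
  metric <- rlang::arg_match(metric)
  stopifnot(fraction > 0, fraction <= 1)
  v <- scores[[metric]]
  ok <- is.finite(v)
  ids <- scores$analyte_id[ok]
  v <- v[ok]
  k <- ceiling(fraction * length(v))
  ids[order(-v, ids)][seq_len(k)]
}

#' Cross-method overlap of top analyte sets
#'
#' Given the top-fraction id sets of two or more metrics, reports every
#' ordered pairwise overlap as a percentage of the first set's size
#' (the natural reading of "x% of the significant genes for method A
#' were identified by method B"), plus the percentage common to all
#' sets.
#'
#' @param sets Named list of non-empty character vectors of analyte
#'   ids.
#' @return A tibble with columns `set_a`, `set_b`, `n_a`, `n_b`,
#'   `n_common`, `pct_of_a`; the all-way intersection is attached as
#'   attribute `triple` (a list with `n_common` and `pct`, the latter
#'   relative to the mean set size).
#' @examples
#' overlap_report(list(fc = c("a", "b", "c", "d"), auc = c("a", "b", "x", "y")))
#' @export
overlap_report <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    rlang::abort("`sets` must be a named list of at least two id sets.",
      class = "bcdscreen_error_bad_input"
    )
  }
  if (any(lengths(sets) == 0)) {
    rlang::abort("Empty id set.", class = "bcdscreen_error_empty_result")
  }
  nm <- names(sets)
  pairs <- expand.grid(set_a = nm, set_b = nm, stringsAsFactors = FALSE) |>
    dplyr::filter(.data$set_a != .data$set_b)
  res <- purrr::pmap_dfr(pairs, function(set_a, set_b) {
    a <- unique(sets[[set_a]])
    b <- unique(sets[[set_b]])
    common <- length(intersect(a, b))
    tibble::tibble(
      set_a = set_a, set_b = set_b,
      n_a = length(a), n_b = length(b), n_common = common,
      pct_of_a = 100 * common / length(a)
    )
  })
  all_common <- Reduce(intersect, lapply(sets, unique))
  attr(res, "triple") <- list(
    n_common = length(all_common),
    pct = 100 * length(all_common) / mean(lengths(lapply(sets, unique)))
  )
  res
}

#' Covariate composition of winsorization-fence hits
#'
#' A second mode that is really a confounded stratum (e.g. one brain
#' region over-represented among cases) shows up as fence-clamped
#' samples concentrated in one covariate level. This diagnostic
#' recomputes the pooled winsorization for one analyte, cross-tabulates
#' the clamped samples by a covariate, and compares each level's share
#' of the clamped set against its share of the whole group, flagging
#' enrichment when the ratio reaches `enrichment_ratio`.
#'
#' @param expr,pheno Expression and phenotype tables (the `screen`
#'   dialect; see [score_analytes()]).
#' @param analyte_id The analyte to interrogate.
#' @param covariate Name of the phenotype covariate column. Missing
#'   covariate values form their own level.
#' @param fence Which fence's hits to cross-tabulate: `"upper"`
#'   (default; the second mode of an upward outlier stratum),
#'   `"lower"`, or `"both"`.
#' @param enrichment_ratio Clamped-share / background-share ratio at or
#'   above which a level is flagged (default 2).
#' @param quartile_type Quantile algorithm for fences.
#' @return A tibble with one row per (group, covariate level) present
#'   among clamped samples: `group`, `level`, `n_clamped`, `n_group`,
#'   `prop_clamped` (share within the group's clamped set),
#'   `prop_background` (level's share of the whole group), `enriched`.
#'   Empty tibble (zero rows) when nothing was clamped.
#' @export
fence_diagnostics <- function(expr, pheno, analyte_id, covariate,
                              fence = c("upper", "lower", "both"),
                              enrichment_ratio = 2, quartile_type = 7) {
  fence <- rlang::arg_match(fence)
  al <- .align_matrix(expr, pheno)
  if (!analyte_id %in% al$analyte_ids) {
    rlang::abort(paste0("Unknown analyte `", analyte_id, "`."),
      class = "bcdscreen_error_bad_input"
    )
  }
  pheno <- tibble::as_tibble(pheno)
  if (!covariate %in% names(pheno)) {
    rlang::abort(paste0("Covariate `", covariate, "` not found."),
      class = "bcdscreen_error_unknown_covariate"
    )
  }
  v <- al$values[analyte_id, ]
  fin <- is.finite(v)
  w <- winsorize(v[fin], ids = al$sample_ids[fin], quartile_type = quartile_type)
  clamped <- switch(fence,
    upper = attr(w, "clamped_high_ids"),
    lower = attr(w, "clamped_low_ids"),
    both = c(attr(w, "clamped_low_ids"), attr(w, "clamped_high_ids"))
  )
  cov_map <- as.character(pheno[[covariate]])[match(al$sample_ids, pheno$sample_id)]
  cov_map[is.na(cov_map)] <- "(missing)"
  grp <- ifelse(al$is_case, "case", "control")
  purrr::map_dfr(c("case", "control"), function(g) {
    in_g <- grp == g
    hits <- intersect(clamped, al$sample_ids[in_g])
    if (length(hits) == 0) return(tibble::tibble())
    hit_lev <- cov_map[match(hits, al$sample_ids)]
    bg <- table(cov_map[in_g]) / sum(in_g)
    tab <- table(hit_lev)
    tibble::tibble(
      group = g,
      level = names(tab),
      n_clamped = as.integer(tab),
      n_group = sum(in_g),
      prop_clamped = as.numeric(tab) / length(hits),
      prop_background = as.numeric(bg[names(tab)])
    ) |>
      dplyr::mutate(
        enriched = .data$prop_clamped >=
          enrichment_ratio * .data$prop_background
      )
  })
}

#' Binned histogram counts for one analyte
#'
#' Exports per-group binned counts of an analyte's (optionally
#' winsorized) values, for external plotting of case/control
#' distributions.
#'
#' @inheritParams fence_diagnostics
#' @param bins Number of equal-width bins over the pooled range.
#' @param winsorized Bin the pooled-winsorized values (default) or the
#'   raw values.
#' @return A tibble with columns `bin_mid`, `bin_lo`, `bin_hi`,
#'   `group`, `count`.
#' @export
analyte_histogram <- function(expr, pheno, analyte_id, bins = 30,
                              winsorized = TRUE, quartile_type = 7) {
  al <- .align_matrix(expr, pheno)
  if (!analyte_id %in% al$analyte_ids) {
    rlang::abort(paste0("Unknown analyte `", analyte_id, "`."),
      class = "bcdscreen_error_bad_input"
    )
  }
  v <- al$values[analyte_id, ]
  fin <- is.finite(v)
  x <- v[fin]
  if (winsorized) x <- as.numeric(winsorize(x, quartile_type = quartile_type))
  grp <- ifelse(al$is_case[fin], "case", "control")
  breaks <- seq(min(x), max(x), length.out = bins + 1)
  purrr::map_dfr(c("case", "control"), function(g) {
    h <- graphics::hist(x[grp == g], breaks = breaks, plot = FALSE)
    tibble::tibble(
      bin_mid = h$mids, bin_lo = utils::head(breaks, -1),
      bin_hi = breaks[-1], group = g, count = h$counts
    )
  })
}
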