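#' Read an expression matrix from tab-separated text
#'
#' Expects the GEO-series-matrix-like dialect after metadata stripping:
#' a header row of sample ids, first column analyte ids, tab-separated,
#' `.` decimal, empty fields for missing values.
#'
#' @param path Path to the TSV file.
#' @return A tibble: first column `analyte_id` (character), one numeric
#'   column per sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Expression file not found: ", path),
      class = "bcdscreen_error_bad_input"
    )
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  names(out)[1] <- "analyte_id"
  out$analyte_id <- as.character(out$analyte_id)
  out
}

#' Read a phenotype table from tab-separated text
#'
#' Columns: `sample_id`, `status` (`case`/`control`), then optional
#' covariates.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Phenotype file not found: ", path),
      class = "bcdscreen_error_bad_input"
    )
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  need <- c("sample_id", "status")
  if (!all(need %in% names(out))) {
    rlang::abort("Phenotype table needs `sample_id` and `status` columns.",
      class = "bcdscreen_error_bad_input"
    )
  }
  out$sample_id <- as.character(out$sample_id)
  out
}

#' Write a fixture (or any expression/phenotype pair) to TSV
#'
#' Writes the two tables in the exact dialect [read_expression()] and
#' [read_phenotypes()] read back: UTF-8, tab-separated, `.` decimal,
#' missing values as empty fields.
#'
#' @param fixture A list with elements `expr` and `pheno` (as returned
#'   by [generate_fixture()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths (`expr`, `pheno`).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_path <- file.path(dir, "expression.tsv")
  pheno_path <- file.path(dir, "phenotypes.tsv")
  readr::write_tsv(fixture$expr, expr_path, na = "")
  readr::write_tsv(fixture$pheno, pheno_path, na = "")
  invisible(list(expr = expr_path, pheno = pheno_path))
}

#' Generate a synthetic case/control expression fixture
#'
#' Builds a genes-by-samples matrix shaped like a cortex expression
#' case/control study (by default 176 cases and 187 controls across
#' four brain regions with realistic case/control imbalance in regions
#' 2 and 4), at a reduced number of analytes. Most analytes are null:
#' values for both groups are Gaussian around a per-analyte baseline
#' intensity. Designated analytes carry planted structure:
#'
#' * **subtype analytes** - a fraction of the cases is drawn from a
#'   second mode at `subtype_shift` times the baseline, the signature
#'   BCD is designed to detect;
#' * **confounded analytes** - samples of one covariate level (both
#'   groups) sit far above the upper winsorization fence, imitating a
#'   stratum-specific expression artifact that manufactures a spurious
#'   second mode.
#'
#' @param n_analytes Number of analytes.
#' @param n_cases,n_controls Samples per group.
#' @param subtype_analytes Tibble (or data frame) with columns
#'   `analyte` (index in 1..n_analytes) and `fraction` (subtype share
#'   of the cases); `NULL` for a fully null matrix.
#' @param confound_analytes Integer indices of analytes given the
#'   covariate-confounded outlier stratum; `NULL` for none.
#' @param confound_level Covariate level (of `region`) carrying the
#'   outlier stratum.
#' @param subtype_shift Multiple of the baseline at which the planted
#'   second mode sits.
#' @param cv Coefficient of variation of the Gaussian noise around each
#'   mode.
#' @param region_probs_cases,region_probs_controls Sampling
#'   probabilities of brain regions 1-4 per group; the defaults
#'   over-represent regions 2 and 4 among cases.
#' @param missing_rate Fraction of entries set missing at random.
#' @param seed Seed; the whole fixture is reproducible from it.
#' @return A list with tibbles `expr` (first column `analyte_id`,
#'   planted analytes named `subtype_*` / `confound_*`, nulls
#'   `null_*`) and `pheno` (`sample_id`, `status`, `region`).
#' @examples
#' fix <- generate_fixture(n_analytes = 20, n_cases = 40, n_controls = 40,
#'                         subtype_analytes = data.frame(analyte = 1,
#'                                                       fraction = 0.3),
#'                         seed = 42)
#' @export
generate_fixture <- function(n_analytes = 50,
                             n_cases = 176, n_controls = 187,
                             subtype_analytes = NULL,
                             confound_analytes = NULL,
                             confound_level = 4,
                             subtype_shift = 3,
                             cv = 0.15,
                             region_probs_cases = c(0.55, 0.20, 0.125, 0.125),
                             region_probs_controls = c(0.65, 0.10, 0.202, 0.048),
                             missing_rate = 0,
                             seed = 1L) {
  stopifnot(n_analytes >= 1, n_cases >= 4, n_controls >= 4,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(subtype_analytes)) {
    subtype_analytes <- tibble::as_tibble(subtype_analytes)
    stopifnot(all(c("analyte", "fraction") %in% names(subtype_analytes)),
              all(subtype_analytes$analyte %in% seq_len(n_analytes)),
              all(subtype_analytes$fraction >= 0),
              all(subtype_analytes$fraction <= 1))
  }
  if (!is.null(confound_analytes)) {
    stopifnot(all(confound_analytes %in% seq_len(n_analytes)))
  }
  set.seed(as.integer(seed) %% 2147483647L)
  n_samp <- n_cases + n_controls
  sample_id <- sprintf("S%04d", seq_len(n_samp))
  status <- rep(c("case", "control"), c(n_cases, n_controls))
  region <- c(
    sample(1:4, n_cases, replace = TRUE, prob = region_probs_cases),
    sample(1:4, n_controls, replace = TRUE, prob = region_probs_controls)
  )
  is_case <- status == "case"

  kind <- rep("null", n_analytes)
  frac <- rep(0, n_analytes)
  if (!is.null(subtype_analytes)) {
    kind[subtype_analytes$analyte] <- "subtype"
    frac[subtype_analytes$analyte] <- subtype_analytes$fraction
  }
  if (!is.null(confound_analytes)) kind[confound_analytes] <- "confound"
  analyte_id <- sprintf("%s_%04d", kind, seq_len(n_analytes))

  m <- matrix(NA_real_, n_analytes, n_samp)
  for (i in seq_len(n_analytes)) {
    base <- stats::runif(1, 50, 500)
    v <- stats::rnorm(n_samp, base, cv * base)
    if (kind[i] == "subtype") {
      n_sub <- round(frac[i] * n_cases)
      idx <- sample(which(is_case), n_sub)
      v[idx] <- stats::rnorm(n_sub, subtype_shift * base,
                             cv * subtype_shift * base)
    } else if (kind[i] == "confound") {
      # the whole stratum, cases and controls alike, sits far beyond
      # the upper 3xIQR fence, so winsorization clamps it to one value
      idx <- which(region == confound_level)
      v[idx] <- stats::rnorm(length(idx), 10 * base, cv * base)
    }
    if (missing_rate > 0) {
      v[stats::runif(n_samp) < missing_rate] <- NA_real_
    }
    m[i, ] <- v
  }
  expr <- tibble::as_tibble(
    stats::setNames(as.data.frame(m), sample_id)
  )
  expr <- dplyr::bind_cols(tibble::tibble(analyte_id = analyte_id), expr)
  pheno <- tibble::tibble(
    sample_id = sample_id, status = status, region = region
  )
  list(expr = expr, pheno = pheno)
}
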