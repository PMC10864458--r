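#' Build a label-by-domain contingency table
#'
#' Cross-tabulates one algorithm's recommendation labels against dataset
#' domains, with the fixed row order medical/biology/general and column
#' order Y/M/No. Only domains and labels that occur are required to be
#' nonzero; a missing domain for a labeled dataset is an error.
#'
#' @param labels Tibble with columns `dataset_name` and `label` for one
#'   algorithm.
#' @param domains Named character vector or tibble (`dataset_name`, `domain`)
#'   mapping datasets to domain tags.
#' @return A `contingency_table` object wrapping the count matrix.
#' @export
build_contingency <- function(labels, domains) {
  if (!nrow(labels)) stop("no labeled datasets", call. = FALSE)
  if (is.data.frame(domains)) {
    domains <- stats::setNames(domains$domain, domains$dataset_name)
  }
  miss <- setdiff(labels$dataset_name, names(domains))
  if (length(miss)) {
    stop("no domain tag for dataset(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dom <- factor(domains[labels$dataset_name], levels = c("medical", "biology", "general"))
  lab <- factor(labels$label, levels = c("Y", "M", "No"))
  counts <- unclass(table(dom, lab))
  new_contingency(counts)
}

new_contingency <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  structure(list(counts = counts, n = sum(counts)), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' Tidy a contingency table
#'
#' @param x A `contingency_table`.
#' @param ... Ignored.
#' @return Tibble with one row per cell (`domain`, `label`, `count`).
#' @export
tidy.contingency_table <- function(x, ...) {
  df <- as.data.frame.table(as.table(x$counts), stringsAsFactors = FALSE)
  names(df) <- c("domain", "label", "count")
  tibble::as_tibble(df)
}

#' R-by-C chi-square statistic
#'
#' Computes the independence statistic in its marginal-products form,
#' `n * (sum_ij A_ij^2 / (n_Ri * n_Cj) - 1)`, which is algebraically equal to
#' the classical Pearson `sum (O - E)^2 / E` with expected counts
#' `E = n_Ri * n_Cj / n`. Rows or columns with zero marginals make the
#' statistic undefined and raise an error rather than being collapsed
#' silently. A message is emitted when any expected count falls below 5,
#' the usual small-sample caveat for tables of this size.
#'
#' @param table A `contingency_table` or a count matrix.
#' @return The chi-square value (`>= 0`).
#' @examples
#' chi_square_rc(rbind(c(1, 2, 2), c(3, 3, 2), c(3, 5, 13)))
#' @export
chi_square_rc <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else as.matrix(table)
  n <- sum(counts)
  r <- rowSums(counts); c <- colSums(counts)
  if (any(r == 0) || any(c == 0)) {
    stop("zero row or column marginal: chi-square undefined", call. = FALSE)
  }
  expected <- outer(r, c) / n
  if (any(expected < 5)) {
    message("chi_square_rc: ", sum(expected < 5), " cell(s) have expected count < 5")
  }
  n * (sum(counts^2 / outer(r, c)) - 1)
}

#' Chi-square significance verdict
#'
#' Compares a chi-square value against the upper-`alpha` quantile of the
#' chi-square distribution with `(rows - 1) * (cols - 1)` degrees of freedom.
#'
#' @param chi2 Chi-square value.
#' @param rows,cols Table dimensions (each `>= 2`).
#' @param alpha Significance level.
#' @return `"different"` or `"not different"`.
#' @export
significance <- function(chi2, rows = 3L, cols = 3L, alpha = 0.05) {
  stopifnot(rows >= 2L, cols >= 2L, chi2 >= 0)
  df <- (rows - 1L) * (cols - 1L)
  if (chi2 > stats::qchisq(1 - alpha, df)) "different" else "not different"
}

#' Domain-difference analysis for every algorithm
#'
#' Builds the label-by-domain table per algorithm, computes the chi-square
#' statistic and its verdict; algorithms whose table has a zero marginal are
#' reported with `NA` and a note instead of failing the whole analysis.
#'
#' @param labels Label tibble from [label_benchmark()] (columns
#'   `dataset_name`, `algorithm`, `label`).
#' @param domains Dataset-to-domain mapping as in [build_contingency()].
#' @param alpha Significance level.
#' @return Tibble with one row per algorithm: `algorithm`, `chi2`, `verdict`.
#' @export
contingency_analysis <- function(labels, domains, alpha = 0.05) {
  labels |>
    dplyr::group_split(.data$algorithm) |>
    purrr::map_dfr(function(g) {
      tab <- build_contingency(g, domains)
      chi2 <- tryCatch(suppressMessages(chi_square_rc(tab)), error = function(e) NA_real_)
      tibble::tibble(
        algorithm = g$algorithm[1],
        chi2 = chi2,
        verdict = if (is.na(chi2)) NA_character_ else {
          significance(chi2, nrow(tab$counts), ncol(tab$counts), alpha)
        }
      )
    })
}
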