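#' Load the published resource-magnitude formula bank
#'
#' Reads the versioned CSV shipped with the package: 48 linear formulas —
#' one per (algorithm, dataset category, target) with target `time` or
#' `memory` — that predict the log10 magnitude of modeling runtime (seconds)
#' and fitted-model memory (bytes, on the original study's hardware) from
#' dataset metafeatures. Coefficients are transcribed verbatim from the
#' published study; an integrity check rejects duplicate or missing keys.
#' The entropy-referencing terms (`E_C`, `ME_V`, `ENV`, `NSR`) assume the
#' metafeature entropies are measured in bits.
#'
#' @param path Optional override of the bank CSV location.
#' @return A `formula_bank` tibble with columns `algorithm`, `category`,
#'   `target`, `term`, `coefficient` and a derived `formula_id`.
#' @export
load_formula_bank <- function(path = NULL) {
  path <- path %||% system.file("extdata", "formula_bank.csv", package = "algsel")
  bank <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("algorithm", "category", "target", "term", "coefficient") %in% names(bank)))
  bank$formula_id <- paste(bank$algorithm, bank$category, bank$target, sep = "_")
  keys <- unique(bank$formula_id)
  expected <- as.vector(outer(
    as.vector(outer(algorithm_ids(), c("mixed", "discrete", "continuous"), paste, sep = "_")),
    c("time", "memory"), paste, sep = "_"))
  if (!setequal(keys, expected) || length(keys) != 48L) {
    stop("formula bank integrity failure: expected the 48 algorithm x category x target keys",
         call. = FALSE)
  }
  dup <- bank |>
    dplyr::count(.data$formula_id, .data$term) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) stop("formula bank integrity failure: duplicated term(s)", call. = FALSE)
  ok_terms <- c("(Intercept)", metafeature_names())
  if (!all(bank$term %in% ok_terms)) {
    stop("formula bank references unknown metafeature(s): ",
         paste(setdiff(bank$term, ok_terms), collapse = ", "), call. = FALSE)
  }
  class(bank) <- c("formula_bank", class(bank))
  attr(bank, "entropy_base") <- 2
  bank
}

bank_formula <- function(bank, algorithm, category, target) {
  dplyr::filter(bank, .data$algorithm == !!algorithm,
                .data$category == !!category, .data$target == !!target)
}

#' Evaluate one linear formula on a metafeature vector
#'
#' `intercept + sum(coefficient * metafeature)`; exactly linear and
#' independent of term order. A referenced metafeature that is missing or
#' non-finite (e.g. an `ENV` flagged as undefined) raises an error naming
#' the feature. A warning is issued when the metafeature vector was computed
#' with an entropy base different from the one the bank assumes.
#'
#' @param formula One formula's rows of a `formula_bank` (single
#'   `formula_id`).
#' @param mf One-row metafeature tibble from [characterize()].
#' @return The predicted log10 magnitude.
#' @export
evaluate_formula <- function(formula, mf) {
  stopifnot(length(unique(formula$formula_id)) == 1L, nrow(mf) == 1L)
  base <- attr(mf, "entropy_base")
  if (!is.null(base) && base != 2) {
    warning("formula bank assumes entropies in bits; metafeatures use base ", base,
            call. = FALSE)
  }
  terms <- formula[formula$term != "(Intercept)", ]
  intercept <- sum(formula$coefficient[formula$term == "(Intercept)"])
  vals <- vapply(terms$term, function(nm) {
    v <- mf[[nm]]
    if (is.null(v) || !is.finite(v)) {
      stop("metafeature '", nm, "' is missing or ineligible for formula evaluation",
           call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  intercept + sum(terms$coefficient * vals)
}

#' Predict per-algorithm resource magnitudes
#'
#' Evaluates the runtime and memory formulas of every algorithm for the
#' given dataset category. The outputs are relative magnitude estimates on
#' the original study's hardware, meant for ranking algorithms, not absolute
#' guarantees.
#'
#' @param mf One-row metafeature tibble.
#' @param category Dataset category (`"mixed"`, `"discrete"`,
#'   `"continuous"`), normally [dataset_category()] of the source dataset.
#' @param bank A loaded [load_formula_bank()] table.
#' @return Tibble of class `resource_prediction`: 8 rows with
#'   `log10_time` and `log10_memory`.
#' @export
predict_resource_magnitudes <- function(mf, category, bank = load_formula_bank()) {
  stopifnot(category %in% c("mixed", "discrete", "continuous"))
  out <- purrr::map_dfr(algorithm_ids(), function(alg) {
    tibble::tibble(
      algorithm = alg,
      category = category,
      log10_time = evaluate_formula(bank_formula(bank, alg, category, "time"), mf),
      log10_memory = evaluate_formula(bank_formula(bank, alg, category, "memory"), mf)
    )
  })
  class(out) <- c("resource_prediction", class(out))
  out
}

#' Plot predicted resource magnitudes
#'
#' @param object A `resource_prediction` tibble.
#' @param ... Ignored.
#' @return A ggplot object with one labeled point per algorithm.
#' @export
autoplot.resource_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log10_time, y = .data$log10_memory,
                                       label = .data$algorithm)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "predicted log10 time (s)", y = "predicted log10 memory (bytes)") +
    ggplot2::theme_minimal()
}

# the published applicability rules; ratio thresholds printed as percentages
# are stored as fractions to match the metafeature scale
applicability_rules <- function() {
  rule <- function(algorithm, category, domain, conditions, verdict, note) {
    list(algorithm = algorithm, category = category, domain = domain,
         conditions = conditions, verdict = verdict, note = note)
  }
  cond <- function(feature, op, threshold) list(feature = feature, op = op, threshold = threshold)
  list(
    rule("AB", "mixed", "medical", list(cond("R_discrete", "<", 0.7778)), "recommended",
         "suitable for medical mixed datasets with discrete-variable ratio below 77.78%"),
    rule("NB", "mixed", "any", list(cond("NSR", ">", -38.7407)), "recommended",
         "suitable when the noise-signal ratio exceeds -38.7407"),
    rule("NB", "discrete", "medical", list(), "recommended",
         "performs markedly better on biomedical-domain discrete datasets than on general ones"),
    rule("NB", "discrete", "biology", list(), "recommended",
         "performs markedly better on biomedical-domain discrete datasets than on general ones"),
    rule("C45", "continuous", "medical", list(cond("P", ">", 15)), "recommended",
         "recommended for medical continuous datasets with more than 15 variables"),
    rule("SVM", "continuous", "medical", list(cond("Var", "<=", 4.5815)), "considered",
         "can be considered when the mean attribute variance is at most 4.5815"),
    rule("RF", "continuous", "medical",
         list(cond("E_C", ">", 0.2383), cond("Geomean", "<=", 0.2241)), "considered",
         "considered when class entropy exceeds 0.2383 and the geometric mean is at most 0.2241")
  )
}

apply_op <- function(value, op, threshold) {
  switch(op,
    "<" = value < threshold, "<=" = value <= threshold,
    ">" = value > threshold, ">=" = value >= threshold,
    "==" = value == threshold,
    stop("unknown comparator: ", op, call. = FALSE))
}

rule_fires <- function(rule, mf, category) {
  if (rule$category != category) return(FALSE)
  if (rule$domain != "any" && !identical(mf$field_label, rule$domain)) return(FALSE)
  all(vapply(rule$conditions, function(cn) {
    v <- mf[[cn$feature]]
    is.finite(v) && apply_op(v, cn$op, cn$threshold)
  }, logical(1)))
}

#' Evaluate the published applicability rules
#'
#' Checks the domain-scoped threshold rules distilled from the original
#' study against a metafeature vector and returns every rule that fires.
#' Percent-scale thresholds are stored as fractions on the metafeature
#' scale. The naive-Bayes advisory on biomedical discrete datasets has no
#' numeric predicate and fires on domain and category alone.
#'
#' @inheritParams predict_resource_magnitudes
#' @return Tibble of fired rules: `algorithm`, `verdict`, `rule`.
#' @export
applicable_rules <- function(mf, category) {
  stopifnot(nrow(mf) == 1L, !is.null(mf$field_label))
  fired <- purrr::keep(applicability_rules(), rule_fires, mf = mf, category = category)
  out <- purrr::map_dfr(fired, function(r) {
    tibble::tibble(algorithm = r$algorithm, verdict = r$verdict, rule = r$note)
  })
  if (!nrow(out)) {
    out <- tibble::tibble(algorithm = character(), verdict = character(), rule = character())
  }
  out
}
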