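# simple rolling hash so every artifact can name the config that produced it
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 1000000007
  sprintf("%08x", as.integer(h))
}

write_artifact <- function(df, path, stage, hash, seed) {
  readr::write_lines(sprintf("# stage=%s config=%s seed=%d", stage, hash, seed), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
}

#' Run the full applicability pipeline
#'
#' Executes preprocess, characterize, benchmark, label, contingency analysis,
#' formula-bank prediction and (when enough datasets are available)
#' meta-learning on a collection of datasets, writing one CSV artifact per
#' stage plus a machine-readable JSON summary into `out_dir`. Every artifact
#' carries a header comment naming the stage, a hash of the effective
#' configuration and the seed, and a rerun with the same configuration and
#' seed reproduces the metafeature and label artifacts byte for byte. A
#' failing stage is recorded in the summary and the stages that need its
#' output are skipped.
#'
#' @param datasets Named list of `algsel_dataset` objects.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param algorithms Algorithms to benchmark.
#' @param limits [resource_limits()] for the benchmark stage.
#' @param alpha Significance level of the contingency analysis.
#' @param min_learn Minimum number of datasets before the meta-learning
#'   stage runs.
#' @return Invisibly, the per-stage status list.
#' @export
run_pipeline <- function(datasets, out_dir, seed = 1L, algorithms = algorithm_ids(),
                         limits = resource_limits(), alpha = 0.05, min_learn = 20L) {
  stopifnot(length(datasets) >= 1L)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- vapply(datasets, dataset_name, character(1))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- list(seed = seed, algorithms = algorithms, limits = unclass(limits),
                 alpha = alpha, min_learn = min_learn)
  hash <- config_hash(config)
  status <- list()
  emit <- function(df, file, stage) write_artifact(df, file.path(out_dir, file), stage, hash, seed)

  # preprocess
  prepped <- purrr::imap(datasets, function(d, nm) {
    tryCatch(preprocess(d), error = function(e) e)
  })
  bad <- names(prepped)[vapply(prepped, inherits, logical(1), "error")]
  status$preprocess <- if (length(bad)) paste("failed for:", paste(bad, collapse = ", ")) else "completed"
  prepped <- prepped[!names(prepped) %in% bad]
  if (!length(prepped)) stop("preprocessing failed for every dataset", call. = FALSE)
  prov <- purrr::imap_dfr(prepped, function(d, nm) {
    p <- attr(d, "provenance")
    tibble::tibble(dataset_name = nm,
                   dropped_columns = paste(p$dropped_columns, collapse = ";"),
                   dropped_rows = length(p$dropped_rows))
  })
  emit(prov, "provenance.csv", "preprocess")

  # characterize
  mf <- purrr::imap_dfr(prepped, function(d, nm) {
    dplyr::bind_cols(tibble::tibble(dataset_name = nm,
                                    category = dataset_category(d)),
                     characterize(d))
  })
  emit(mf, "metafeatures.csv", "characterize")
  status$characterize <- "completed"

  # benchmark + label
  records <- benchmark_suite(prepped, algorithms, limits = limits, seed = seed)
  emit(records, "benchmark.csv", "benchmark")
  status$benchmark <- "completed"
  labels <- label_benchmark(records)
  # the label matrix is the contract; ranks depend on wall-clock tie-breaks,
  # so the artifact is sorted by the fixed algorithm order instead
  label_matrix <- labels[, c("dataset_name", "algorithm", "status", "label", "recommended")]
  label_matrix <- label_matrix[order(label_matrix$dataset_name,
                                     match(label_matrix$algorithm, algorithm_ids())), ]
  emit(label_matrix, "labels.csv", "label")
  status$label <- "completed"

  # contingency
  domains <- vapply(prepped, dataset_domain, character(1))
  cont <- tryCatch(contingency_analysis(labels, domains, alpha = alpha),
                   error = function(e) e)
  if (inherits(cont, "error")) {
    status$contingency <- paste("failed:", conditionMessage(cont))
  } else {
    emit(cont, "contingency.csv", "contingency")
    status$contingency <- "completed"
  }

  # formula-bank predictions
  bank <- load_formula_bank()
  preds <- purrr::imap_dfr(prepped, function(d, nm) {
    row <- mf[mf$dataset_name == nm, ]
    dplyr::bind_cols(tibble::tibble(dataset_name = nm),
                     predict_resource_magnitudes(row, row$category[1], bank))
  })
  emit(preds, "predictions.csv", "predict")
  status$predict <- "completed"

  # meta-learning over the run's own metadata
  learn <- purrr::map_dfr(algorithms, function(alg) {
    lab <- labels[labels$algorithm == alg, ]
    meta <- dplyr::inner_join(mf, lab[, c("dataset_name", "recommended")], by = "dataset_name")
    meta$target <- ifelse(meta$recommended, "Y", "No")
    meta <- meta[, c(metafeature_names(), "target")]
    meta <- meta[vapply(meta, function(c) all(is.finite(c) | !is.numeric(c)), logical(1))]
    if (nrow(meta) < min_learn || length(unique(meta$target)) < 2L) {
      return(tibble::tibble(algorithm = alg, cv_accuracy = NA_real_,
                            note = "skipped: insufficient metadata"))
    }
    acc <- tryCatch(
      suppressWarnings(cross_validate(meta, learner = "tree",
                                      k = min(10L, nrow(meta) %/% 2L), seed = seed)),
      error = function(e) NA_real_)
    tibble::tibble(algorithm = alg, cv_accuracy = as.numeric(acc), note = "")
  })
  emit(learn, "learn_cv.csv", "learn")
  status$learn <- if (all(learn$note == "")) "completed" else "partial"

  summary <- list(config = config, config_hash = hash, stages = status,
                  n_datasets = length(prepped),
                  fired_rules = purrr::imap(prepped, function(d, nm) {
                    row <- mf[mf$dataset_name == nm, ]
                    as.list(applicable_rules(row, row$category[1]))
                  }))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(status)
}
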