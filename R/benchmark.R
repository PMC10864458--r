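#' The eight base algorithm identifiers
#'
#' Logistic regression (LR), decision tree (C45), support vector machine
#' (SVM), AdaBoost (AB), k-nearest neighbours (kNN), naive Bayes (NB),
#' random forest (RF) and a single-hidden-layer backpropagation network (BP),
#' in the fixed order used for tie-breaking.
#' @return Character vector of length 8.
#' @export
algorithm_ids <- function() c("LR", "C45", "SVM", "AB", "kNN", "NB", "RF", "BP")

#' Resource limits for benchmarking
#'
#' The original study's numeric limits are not published; these defaults are
#' deliberate, documented stand-ins sized for desk-scale runs. The dummy
#' coefficient cap guards the weight-based learners (LR, BP) against one-hot
#' blow-ups of high-cardinality discrete attributes; the category cap mirrors
#' the random-forest implementation's hard limit on factor levels.
#'
#' @param timeout_seconds Wall-clock fitting budget per model.
#' @param memory_cap_bytes Upper bound on the serialized fitted-model size.
#' @param max_dummy_coefficients Largest one-hot design width allowed for LR
#'   and BP before a `dimension_limit` failure.
#' @param max_category_levels Largest factor cardinality allowed for RF
#'   before a `category_limit` failure.
#' @return A list of class `resource_limits`.
#' @export
resource_limits <- function(timeout_seconds = 300, memory_cap_bytes = 512 * 1024^2,
                            max_dummy_coefficients = 1000L, max_category_levels = 53L) {
  stopifnot(timeout_seconds > 0, memory_cap_bytes > 0,
            max_dummy_coefficients > 0, max_category_levels > 0)
  structure(list(timeout_seconds = timeout_seconds,
                 memory_cap_bytes = memory_cap_bytes,
                 max_dummy_coefficients = as.integer(max_dummy_coefficients),
                 max_category_levels = as.integer(max_category_levels)),
            class = "resource_limits")
}

#' Recall of the largest class
#'
#' The multiclass analogue of sensitivity: the percentage of samples in the
#' most frequent true class that were predicted correctly. Ties on the most
#' frequent class are broken by label sort order.
#'
#' @param y_true,y_pred Equal-length class vectors.
#' @return Percentage in `[0, 100]`.
#' @export
s_largest <- function(y_true, y_pred) class_recall(y_true, y_pred, which.max)

#' Recall of the smallest class
#'
#' The multiclass analogue of specificity for the rare class: the percentage
#' of samples in the least frequent true class predicted correctly.
#'
#' @inheritParams s_largest
#' @return Percentage in `[0, 100]`.
#' @export
s_least <- function(y_true, y_pred) class_recall(y_true, y_pred, which.min)

class_recall <- function(y_true, y_pred, pick) {
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ", call. = FALSE)
  if (!length(y_true)) stop("empty class vector", call. = FALSE)
  counts <- table(y_true)
  target <- names(counts)[pick(counts)]  # which.max/min take the first = sorted label order on ties
  in_class <- as.character(y_true) == target
  100 * mean(as.character(y_pred)[in_class] == target)
}

stratified_split <- function(y, train_frac = 0.7) {
  idx <- seq_along(y)
  train <- unlist(lapply(split(idx, y), function(i) {
    k <- max(1L, round(length(i) * train_frac))
    if (length(i) == 1L) i else sample(i, k)
  }), use.names = FALSE)
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}

# design helpers ----------------------------------------------------------

as_model_frame <- function(data) {
  kinds <- dataset_kinds(data)
  df <- as.data.frame(data[names(kinds)])
  for (nm in names(kinds)) {
    if (kinds[[nm]] != "continuous") df[[nm]] <- factor(df[[nm]])
    else df[[nm]] <- as.numeric(df[[nm]])
  }
  df$.class <- factor(data[[dataset_class(data)]])
  df
}

one_hot <- function(df) {
  stats::model.matrix(~ . - 1, data = df[setdiff(names(df), ".class")])
}

# learners: each returns list(model, predict = function(newdata) factor)
fit_learner <- function(algorithm, train, test, limits) {
  y <- train$.class
  lev <- levels(y)
  switch(algorithm,
    LR = {
      fit <- nnet::multinom(.class ~ ., data = train, trace = FALSE, maxit = 200,
                            MaxNWts = 1e6)
      list(model = fit, pred = function(nd) factor(predict(fit, nd), levels = lev))
    },
    C45 = {
      fit <- rpart::rpart(.class ~ ., data = train, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(cp = 0.01, minsplit = 10))
      list(model = fit, pred = function(nd) factor(predict(fit, nd, type = "class"), levels = lev))
    },
    SVM = {
      fit <- e1071::svm(.class ~ ., data = train, kernel = "radial")
      list(model = fit, pred = function(nd) factor(predict(fit, nd), levels = lev))
    },
    AB = {
      fit <- ada_fit(train[setdiff(names(train), ".class")], y, n_rounds = 30L, maxdepth = 2L)
      list(model = fit, pred = function(nd) ada_predict(fit, nd[setdiff(names(nd), ".class")]))
    },
    kNN = {
      Xtr <- one_hot(train); Xte <- one_hot(test)
      mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd); sdv[sdv == 0] <- 1
      Xtr <- scale(Xtr, mu, sdv)
      # the training matrix is the model: kNN defers all work to query time
      list(model = list(X = Xtr, y = y),
           pred = function(nd) {
             Xq <- scale(one_hot(nd)[, colnames(Xtr), drop = FALSE], mu, sdv)
             factor(class::knn(Xtr, Xq, y, k = 5), levels = lev)
           })
    },
    NB = {
      fit <- e1071::naiveBayes(.class ~ ., data = train)
      list(model = fit, pred = function(nd) factor(predict(fit, nd), levels = lev))
    },
    RF = {
      fit <- randomForest::randomForest(.class ~ ., data = train, ntree = 100)
      list(model = fit, pred = function(nd) factor(predict(fit, nd), levels = lev))
    },
    BP = {
      Xtr <- one_hot(train)
      fit <- nnet::nnet(Xtr, stats::model.matrix(~ y - 1), size = 8, decay = 0.01,
                        maxit = 200, trace = FALSE, softmax = TRUE, MaxNWts = 1e6)
      list(model = fit,
           pred = function(nd) {
             p <- predict(fit, one_hot(nd)[, colnames(Xtr), drop = FALSE])
             factor(lev[max.col(p)], levels = lev)
           })
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

# SAMME multi-class AdaBoost over shallow rpart trees
ada_fit <- function(X, y, n_rounds = 30L, maxdepth = 2L) {
  n <- length(y); k <- nlevels(y)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric()
  df <- cbind(X, .y = y)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth, cp = -1,
                                                       minsplit = 5, xval = 0))
    pred <- predict(fit, df, type = "class")
    mis <- pred != y
    err <- sum(w[mis])
    if (err <= 1e-10) { trees[[t]] <- fit; alphas[t] <- 10; break }
    if (err >= 1 - 1 / k) break
    alpha <- log((1 - err) / err) + log(k - 1)
    trees[[t]] <- fit; alphas[t] <- alpha
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  if (!length(trees)) {  # no usable round: fall back to the prior
    trees <- list(NULL); alphas <- 1
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y),
                 prior = names(sort(table(y), decreasing = TRUE))[1]),
            class = "algsel_ada")
}

ada_predict <- function(object, X) {
  lev <- object$levels
  votes <- matrix(0, nrow(X), length(lev), dimnames = list(NULL, lev))
  for (i in seq_along(object$trees)) {
    fit <- object$trees[[i]]
    if (is.null(fit)) { votes[, object$prior] <- votes[, object$prior] + 1; next }
    p <- as.character(predict(fit, X, type = "class"))
    votes[cbind(seq_len(nrow(X)), match(p, lev))] <-
      votes[cbind(seq_len(nrow(X)), match(p, lev))] + object$alphas[i]
  }
  factor(lev[max.col(votes)], levels = lev)
}

failed_record <- function(algorithm, data, reason, seed) {
  tibble::tibble(
    algorithm = algorithm, dataset_name = dataset_name(data),
    category = dataset_category(data), status = "failed", failure_reason = reason,
    acc_train = NA_real_, acc_test = NA_real_, s_largest = NA_real_,
    s_least = NA_real_, time_seconds = NA_real_, log10_time = NA_real_,
    model_bytes = NA_real_, log10_memory = NA_real_, seed = seed
  )
}

#' Benchmark one algorithm on one dataset
#'
#' Stratified holdout split, resource-limit pre-checks, timed fit, serialized
#' model size, and test-partition metrics. Limit violations and runtime
#' faults are captured in the record's failure taxonomy — `dimension_limit`
#' (one-hot design too wide for the weight-based learners), `category_limit`
#' (a discrete attribute with too many levels for RF), `memory_limit`,
#' `timeout`, `numeric_error` — and never raised. Modeling time is wall-clock
#' seconds of the fit alone (floored at 0.1 ms against timer resolution);
#' memory is the serialized fitted-model size in bytes; both are also
#' reported on the log10 scale on which magnitudes are compared.
#'
#' @param data A preprocessed `algsel_dataset` with at least two classes.
#' @param algorithm One of [algorithm_ids()].
#' @param train_frac Training fraction of the stratified holdout split.
#' @param limits A [resource_limits()] object.
#' @param seed Integer seed controlling the split and any learner randomness.
#' @return One-row tibble (a `PerformanceRecord`).
#' @export
evaluate_algorithm <- function(data, algorithm, train_frac = 0.7,
                               limits = resource_limits(), seed = 1L) {
  stopifnot(inherits(data, "algsel_dataset"), algorithm %in% algorithm_ids(),
            inherits(limits, "resource_limits"))
  df <- as_model_frame(data)
  if (nlevels(df$.class) < 2L) stop("benchmarking needs at least 2 classes", call. = FALSE)
  set.seed(seed)
  idx <- stratified_split(df$.class, train_frac)
  train <- df[idx$train, , drop = FALSE]
  test <- df[idx$test, , drop = FALSE]

  # pre-checks per the failure taxonomy
  if (algorithm %in% c("LR", "BP")) {
    width <- ncol(one_hot(df)) + 1L
    if (width > limits$max_dummy_coefficients) {
      return(failed_record(algorithm, data, "dimension_limit", seed))
    }
  }
  if (algorithm == "RF") {
    lv <- vapply(df[setdiff(names(df), ".class")],
                 function(col) if (is.factor(col)) nlevels(col) else 0L, integer(1))
    if (any(lv > limits$max_category_levels)) {
      return(failed_record(algorithm, data, "category_limit", seed))
    }
  }

  fit_res <- tryCatch({
    t0 <- proc.time()[["elapsed"]]
    setTimeLimit(elapsed = limits$timeout_seconds, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    learner <- fit_learner(algorithm, train, test, limits)
    elapsed <- proc.time()[["elapsed"]] - t0
    setTimeLimit(elapsed = Inf)
    list(learner = learner, elapsed = elapsed)
  }, error = function(e) {
    if (grepl("time limit|elapsed", conditionMessage(e))) "timeout" else "numeric_error"
  })
  if (is.character(fit_res)) return(failed_record(algorithm, data, fit_res, seed))
  # non-interruptible fits are still held to the budget after the fact
  if (fit_res$elapsed > limits$timeout_seconds) {
    return(failed_record(algorithm, data, "timeout", seed))
  }

  bytes <- length(serialize(fit_res$learner$model, NULL))
  if (bytes > limits$memory_cap_bytes) {
    return(failed_record(algorithm, data, "memory_limit", seed))
  }
  metrics <- tryCatch({
    pred_tr <- fit_res$learner$pred(train)
    pred_te <- fit_res$learner$pred(test)
    list(
      acc_train = mean(pred_tr == train$.class),
      acc_test = mean(pred_te == test$.class),
      s_largest = s_largest(test$.class, pred_te),
      s_least = s_least(test$.class, pred_te)
    )
  }, error = function(e) NULL)
  if (is.null(metrics)) return(failed_record(algorithm, data, "numeric_error", seed))

  secs <- max(fit_res$elapsed, 1e-4)
  tibble::tibble(
    algorithm = algorithm, dataset_name = dataset_name(data),
    category = dataset_category(data), status = "completed", failure_reason = "none",
    acc_train = metrics$acc_train, acc_test = metrics$acc_test,
    s_largest = metrics$s_largest, s_least = metrics$s_least,
    time_seconds = secs, log10_time = log10(secs),
    model_bytes = bytes, log10_memory = log10(bytes), seed = seed
  )
}

#' Benchmark a collection of datasets
#'
#' One performance record per (dataset, algorithm) pair; each pair gets a
#' deterministic seed derived from `seed`, so a rerun with the same seed
#' reproduces every accuracy field.
#'
#' @param datasets List of preprocessed `algsel_dataset` objects.
#' @param algorithms Subset of [algorithm_ids()].
#' @param train_frac,limits Passed to [evaluate_algorithm()].
#' @param seed Base integer seed.
#' @return Tibble of class `algsel_benchmark`.
#' @export
benchmark_suite <- function(datasets, algorithms = algorithm_ids(),
                            train_frac = 0.7, limits = resource_limits(), seed = 1L) {
  stopifnot(all(algorithms %in% algorithm_ids()))
  grid <- expand.grid(d = seq_along(datasets), a = seq_along(algorithms))
  out <- purrr::pmap_dfr(grid, function(d, a) {
    evaluate_algorithm(datasets[[d]], algorithms[[a]], train_frac, limits,
                       seed = seed + 1009L * d + a)
  })
  class(out) <- c("algsel_benchmark", class(out))
  out
}

#' Summarize completions and failures by dataset category
#'
#' Collapses a benchmark table to the algorithm-by-category layout of
#' completed/failed counts plus a total-failed column.
#'
#' @param records A benchmark tibble.
#' @return Tibble with one row per algorithm.
#' @export
benchmark_summary <- function(records) {
  records |>
    dplyr::group_by(.data$algorithm, .data$category) |>
    dplyr::summarise(completed = sum(.data$status == "completed"),
                     failed = sum(.data$status == "failed"), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category",
                       values_from = c("completed", "failed"), values_fill = 0L) |>
    dplyr::mutate(total_failed = rowSums(dplyr::across(dplyr::starts_with("failed"))))
}

#' Scatter the resource profile of a benchmark run
#'
#' log10 modeling time against log10 model memory, one point per completed
#' (dataset, algorithm) record, coloured by algorithm — the per-run analogue
#' of the study-wide resource scatter views.
#'
#' @param object An `algsel_benchmark` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.algsel_benchmark <- function(object, ...) {
  done <- dplyr::filter(object, .data$status == "completed")
  ggplot2::ggplot(done, ggplot2::aes(x = .data$log10_time, y = .data$log10_memory,
                                     colour = .data$algorithm)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "log10 modeling time (s)", y = "log10 model memory (bytes)",
                  colour = "algorithm") +
    ggplot2::theme_minimal()
}
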