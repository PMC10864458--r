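test_that("the correlation pre-filter keeps marginally correlated features", {
  set.seed(41)
  n <- 200
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rep(1, n))
  df$dup <- df$x1
  df$target <- 2 * df$x1
  keep <- correlation_prefilter(df)
  expect_true("x1" %in% keep)
  expect_false("x2" %in% keep)
  expect_false("x3" %in% keep)            # constant: r treated as 0
  expect_true("dup" %in% keep)            # marginal filter keeps duplicates
  expect_equal(correlation_prefilter(df, threshold = 1.0), character(0))
})

test_that("stepwise selection recovers a single generating feature and stays quiet on noise", {
  hits <- 0L; exact <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    df <- tibble::as_tibble(stats::setNames(
      lapply(1:6, function(i) rnorm(n)), paste0("x", 1:6)))
    df$target <- 3 * df$x1 + rnorm(n, sd = 0.5)
    fit <- stepwise_select(df)
    hits <- hits + ("x1" %in% fit$selected_features)
    exact <- exact + identical(fit$selected_features, "x1")
    expect_lte(length(setdiff(fit$selected_features, "x1")), 2L)
  }
  expect_equal(hits, 20L)
  # spurious entries occur at roughly the per-candidate alpha rate
  expect_gte(exact, 12L)

  # pure-noise target: empty selection at about (1 - alpha)^p
  empty <- 0L
  for (s in 1:30) {
    set.seed(100 + s)
    df <- tibble::as_tibble(stats::setNames(lapply(1:4, function(i) rnorm(80)),
                                            paste0("x", 1:4)))
    df$target <- rnorm(80)
    empty <- empty + (length(stepwise_select(df)$selected_features) == 0L)
  }
  # expect around 0.95^4 = 0.81 of 30; allow a generous binomial band
  expect_gte(empty, 18L)

  # p_enter = 0 admits nothing
  df <- tibble::tibble(x1 = rnorm(50), target = rnorm(50))
  expect_length(stepwise_select(df, p_enter = 0, p_remove = 0)$selected_features, 0L)
})

test_that("the stepwise trace replays to the final selection", {
  md <- recovery_metadata(seed = 3L)
  fit <- suppressWarnings(stepwise_select(md))
  replay <- character()
  for (i in seq_len(nrow(fit$trace))) {
    ev <- fit$trace[i, ]
    replay <- if (ev$action == "add") sort(c(replay, ev$feature))
              else setdiff(replay, ev$feature)
  }
  expect_equal(sort(replay), sort(fit$selected_features))
  expect_true(all(fit$selected_features %in% fit$feature_names))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 500L)
})

test_that("gain ratio at the root matches exhaustive enumeration on a small table", {
  # 8-row table with one numeric and one categorical feature
  df <- tibble::tibble(
    num = c(1, 2, 3, 4, 5, 6, 7, 8),
    cat = c("u", "u", "v", "v", "u", "v", "u", "v"),
    target = c("a", "a", "a", "b", "b", "b", "b", "b")
  )
  tree <- build_c45_tree(df, min_leaf = 1L, prune = FALSE)

  h <- function(counts) entropy_oracle(counts)
  n <- nrow(df)
  parent <- h(table(df$target))
  best <- list(gr = -Inf)
  for (t in (df$num[-n] + df$num[-1]) / 2) {     # all midpoints
    left <- df$target[df$num <= t]; right <- df$target[df$num > t]
    if (!length(left) || !length(right)) next
    gain <- parent - length(left) / n * h(table(left)) - length(right) / n * h(table(right))
    si <- h(c(length(left), length(right)))
    if (si > 0 && gain > 1e-12 && gain / si > best$gr) {
      best <- list(gr = gain / si, feature = "num", threshold = t)
    }
  }
  sizes <- table(df$cat)
  gain_cat <- parent - sum(vapply(names(sizes), function(v) {
    sum(df$cat == v) / n * h(table(df$target[df$cat == v]))
  }, numeric(1)))
  si_cat <- h(as.vector(sizes))
  if (gain_cat / si_cat > best$gr) best <- list(gr = gain_cat / si_cat, feature = "cat")

  expect_equal(tree$root$feature, best$feature)
  if (best$feature == "num") expect_equal(tree$root$threshold, best$threshold)
})

test_that("a planted axis-aligned rule yields a depth-1 tree with a perfect holdout", {
  md <- generate_meta_dataset(planted_rule_p15(), n = 300L, label_noise = 0, seed = 2L)
  tree <- build_c45_tree(md)
  expect_equal(tree$root$feature, "P")
  expect_lt(abs(tree$root$threshold - 15), 1.5)
  expect_equal(glance(tree)$depth, 1L)
  holdout <- generate_meta_dataset(planted_rule_p15(), n = 200L, label_noise = 0, seed = 99L)
  expect_equal(mean(predict_tree(tree, holdout) == holdout$target), 1.0)

  # single-class input: a single leaf, no error
  one <- md; one$target <- "Y"
  t1 <- build_c45_tree(one)
  expect_equal(t1$root$type, "leaf")
  expect_equal(unique(predict_tree(t1, md)), "Y")
})

test_that("tree prediction descends thresholds consistently and names missing features", {
  md <- generate_meta_dataset(planted_rule_p15(), n = 200L, label_noise = 0, seed = 5L)
  tree <- build_c45_tree(md)
  grid <- md[1, ]
  for (p in c(10, 14, 16, 40)) {
    grid$P <- p
    expect_equal(predict_tree(tree, grid),
                 if (p > tree$root$threshold) "Y" else "No")
  }
  expect_error(predict_tree(tree, md[1, setdiff(names(md), "P")]), "P")
})

test_that("pruning never beats the unpruned tree on training data, and both beat the majority", {
  md <- generate_meta_dataset(planted_rule_p15(), n = 250L, label_noise = 0.15, seed = 8L)
  full <- build_c45_tree(md, prune = FALSE)
  pruned <- build_c45_tree(md, prune = TRUE)
  acc_full <- mean(predict_tree(full, md) == md$target)
  acc_pruned <- mean(predict_tree(pruned, md) == md$target)
  majority <- max(table(md$target)) / nrow(md)
  expect_gte(acc_full, acc_pruned)
  expect_gte(acc_pruned, majority)
  expect_lte(glance(pruned)$leaf_count, glance(full)$leaf_count)
})

test_that("cross-validation is stratified, deterministic, and supports both learners", {
  md <- generate_meta_dataset(planted_rule_p15(), n = 120L, label_noise = 0, seed = 6L)
  acc <- cross_validate(md, learner = "tree", k = 5L, seed = 3L)
  expect_equal(as.numeric(acc), 1.0)    # separable
  expect_equal(as.numeric(cross_validate(md, learner = "tree", k = 5L, seed = 3L)),
               as.numeric(acc))

  # leave-one-out on a small set returns a fraction
  small <- md[1:30, ]
  loo <- cross_validate(small, learner = "tree", k = 30L, seed = 1L)
  expect_true(as.numeric(loo) >= 0 && as.numeric(loo) <= 1)

  acc_sw <- suppressWarnings(cross_validate(md, learner = "stepwise", k = 5L, seed = 3L))
  expect_gte(as.numeric(acc_sw), 0.8)
})
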