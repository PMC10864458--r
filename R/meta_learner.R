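#' Correlation pre-filter for magnitude targets
#'
#' Keeps the features whose absolute Pearson correlation with a real-valued
#' target strictly exceeds the threshold — the marginal screening step run
#' before stepwise modeling of log10 runtime/memory targets. Constant and
#' non-numeric features have undefined correlation and are treated as 0.
#'
#' @param data Data frame of features plus the target column.
#' @param target Name of the (numeric) target column.
#' @param threshold Absolute-correlation cutoff.
#' @return Character vector of retained feature names.
#' @export
correlation_prefilter <- function(data, target = "target", threshold = 0.3) {
  stopifnot(target %in% names(data), is.numeric(data[[target]]))
  y <- data[[target]]
  feats <- setdiff(names(data), target)
  r <- vapply(feats, function(nm) {
    x <- data[[nm]]
    if (!is.numeric(x) || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    abs(stats::cor(x, y))
  }, numeric(1))
  feats[r > threshold]
}

expand_features <- function(data, feats) {
  cols <- list()
  for (nm in feats) {
    x <- data[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(x)
    } else {
      f <- factor(x)
      for (lv in levels(f)[-1]) cols[[paste0(nm, "=", lv)]] <- as.numeric(f == lv)
    }
  }
  as.data.frame(cols, check.names = FALSE, optional = TRUE)
}

#' Bidirectional stepwise regression
#'
#' Classic p-value-driven stepwise selection: at each round the candidate
#' with the smallest partial-F p-value enters if it beats `p_enter`, then any
#' included feature whose p-value has risen above `p_remove` leaves, until a
#' fixed point. Fits are ordinary least squares (a linear probability model
#' when the target is a 0/1 recommendation indicator); `family = "logistic"`
#' switches to a binomial GLM with Wald z-tests. Categorical features are
#' expanded to treatment dummies up front; ties and iteration order follow
#' lexicographic feature order, so the procedure is deterministic. A
#' candidate that makes the design rank-deficient is skipped with a warning.
#'
#' @param data Data frame of features plus the target column.
#' @param target Name of the target column (numeric; 0/1 for the binary
#'   recommendation framing).
#' @param p_enter Entry p-value threshold.
#' @param p_remove Removal p-value threshold (`>= p_enter` to avoid cycling).
#' @param family `"linear"` (default) or `"logistic"`.
#' @return An object of class `stepwise_fit` with the selected features, the
#'   final fit, and an add/remove trace.
#' @export
stepwise_select <- function(data, target = "target", p_enter = 0.05,
                            p_remove = 0.10, family = c("linear", "logistic")) {
  family <- match.arg(family)
  stopifnot(target %in% names(data), p_enter >= 0, p_remove >= p_enter)
  y <- data[[target]]
  if (!is.numeric(y)) stop("stepwise target must be numeric (code labels 0/1 first)", call. = FALSE)
  X <- expand_features(data, setdiff(names(data), target))
  X <- X[, sort(names(X)), drop = FALSE]
  candidates <- names(X)
  included <- character()
  trace <- list()
  fit_model <- function(feats) {
    df <- cbind(X[feats], .y = y)
    if (family == "linear") stats::lm(.y ~ ., data = df) else
      stats::glm(.y ~ ., data = df, family = stats::binomial())
  }
  pvals <- function(fit) {
    cf <- summary(fit)$coefficients
    p <- cf[, 4]
    names(p) <- gsub("`", "", rownames(cf))
    p[setdiff(names(p), "(Intercept)")]
  }
  term_of <- identity
  for (iter in seq_len(2L * length(candidates) + 2L)) {
    changed <- FALSE
    # forward: best candidate by partial-F (t^2) p-value
    pool <- setdiff(candidates, included)
    if (length(pool) && length(y) > length(included) + 3L) {
      entry <- vapply(pool, function(cand) {
        fit <- fit_model(c(included, cand))
        if (anyNA(stats::coef(fit))) {
          warning("stepwise: skipping rank-deficient candidate '", cand, "'", call. = FALSE)
          return(NA_real_)
        }
        p <- pvals(fit)
        unname(p[term_of(cand)])
      }, numeric(1))
      if (any(!is.na(entry)) && min(entry, na.rm = TRUE) < p_enter) {
        best <- pool[which.min(entry)]  # first minimum = lexicographic tie-break
        included <- sort(c(included, best))
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = length(trace) + 1L, action = "add", feature = best,
          p_value = min(entry, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward: drop whatever no longer earns its place
    while (length(included)) {
      p <- pvals(fit_model(included))
      p <- p[term_of(included)]
      if (all(is.na(p)) || max(p, na.rm = TRUE) <= p_remove) break
      worst <- included[which.max(p)]
      included <- setdiff(included, worst)
      trace[[length(trace) + 1L]] <- tibble::tibble(
        step = length(trace) + 1L, action = "remove", feature = worst,
        p_value = max(p, na.rm = TRUE))
      changed <- TRUE
    }
    if (!changed) break
  }
  final <- if (length(included)) fit_model(included) else {
    if (family == "linear") stats::lm(y ~ 1) else stats::glm(y ~ 1, family = stats::binomial())
  }
  structure(list(
    selected_features = included,
    fit = final,
    family = family,
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), action = character(),
                     feature = character(), p_value = numeric()),
    feature_names = candidates,
    n = length(y)
  ), class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> ", x$family, " model, ", length(x$selected_features),
      " feature(s) selected of ", length(x$feature_names), "\n", sep = "")
  if (length(x$selected_features)) cat("  ", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a stepwise fit
#' @param x A `stepwise_fit`.
#' @param ... Ignored.
#' @return Coefficient tibble (`term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`).
#' @export
tidy.stepwise_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = gsub("`", "", rownames(cf)), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
}

#' One-row summary of a stepwise fit
#' @param x A `stepwise_fit`.
#' @param ... Ignored.
#' @return Tibble with fit-level statistics.
#' @export
glance.stepwise_fit <- function(x, ...) {
  r2 <- if (x$family == "linear") summary(x$fit)$r.squared else NA_real_
  tibble::tibble(n = x$n, n_selected = length(x$selected_features),
                 n_steps = nrow(x$trace), r.squared = r2)
}

# --- gain-ratio decision tree -------------------------------------------

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# vectorized search over midpoints between sorted distinct values
best_numeric_split <- function(x, y, min_leaf) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  lev <- levels(ys)
  cum <- vapply(lev, function(l) cumsum(ys == l), numeric(n))
  total <- cum[n, ]
  cand <- which(xs[-n] < xs[-1])
  cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
  if (!length(cand)) return(NULL)
  left <- cum[cand, , drop = FALSE]
  right <- rep(total, each = length(cand)) - left
  h_of <- function(m) {
    tot <- rowSums(m)
    p <- m / tot
    lp <- p * log2(p)
    lp[!is.finite(lp)] <- 0
    -rowSums(lp)
  }
  nl <- cand; nr <- n - cand
  h_parent <- entropy_counts(total)
  gain <- h_parent - (nl / n) * h_of(left) - (nr / n) * h_of(right)
  split_info <- -(nl / n) * log2(nl / n) - (nr / n) * log2(nr / n)
  gr <- ifelse(split_info > 0 & gain > 1e-12, gain / split_info, -Inf)
  best <- which.max(gr)
  if (!is.finite(gr[best])) return(NULL)
  i <- cand[best]
  list(threshold = (xs[i] + xs[i + 1]) / 2, gain_ratio = gr[best], gain = gain[best])
}

best_categorical_split <- function(x, y, min_leaf) {
  tab <- table(x, y)
  sizes <- rowSums(tab)
  if (sum(sizes > 0) < 2L || sum(sizes >= min_leaf) < 2L) return(NULL)
  n <- length(x)
  h_parent <- entropy_counts(table(y))
  h_children <- apply(tab, 1, entropy_counts)
  gain <- h_parent - sum(sizes / n * h_children)
  split_info <- entropy_counts(sizes)
  if (split_info <= 0 || gain <= 1e-12) return(NULL)
  list(values = rownames(tab)[sizes > 0], gain_ratio = gain / split_info, gain = gain)
}

majority <- function(y) {
  tab <- table(y)
  names(tab)[which.max(tab)]  # ties: first in sorted label order
}

grow_tree <- function(X, y, min_leaf, depth) {
  dist <- table(y)
  leaf <- function() list(type = "leaf", label = majority(y),
                          dist = as.vector(dist), classes = names(dist),
                          n = length(y), errors = length(y) - max(dist))
  if (length(unique(y[!is.na(y)])) <= 1L || length(y) < 2L * min_leaf || depth > 30L) {
    return(leaf())
  }
  splits <- purrr::compact(purrr::imap(X, function(col, nm) {
    s <- if (is.numeric(col)) best_numeric_split(col, y, min_leaf)
         else best_categorical_split(col, y, min_leaf)
    if (is.null(s)) NULL else c(list(feature = nm), s)
  }))
  if (!length(splits)) return(leaf())
  gr <- vapply(splits, `[[`, numeric(1), "gain_ratio")
  s <- splits[[which.max(gr)]]
  if (!is.null(s$threshold)) {
    go_left <- X[[s$feature]] <= s$threshold
    children <- list(
      "<=" = grow_tree(X[go_left, , drop = FALSE], factor(y[go_left]), min_leaf, depth + 1L),
      ">"  = grow_tree(X[!go_left, , drop = FALSE], factor(y[!go_left]), min_leaf, depth + 1L)
    )
    list(type = "split", feature = s$feature, kind = "numeric",
         threshold = s$threshold, children = children,
         label = majority(y), n = length(y), errors = length(y) - max(dist),
         dist = as.vector(dist), classes = names(dist))
  } else {
    children <- lapply(s$values, function(v) {
      in_branch <- as.character(X[[s$feature]]) == v
      grow_tree(X[in_branch, , drop = FALSE], factor(y[in_branch]), min_leaf, depth + 1L)
    })
    names(children) <- s$values
    list(type = "split", feature = s$feature, kind = "categorical",
         children = children, label = majority(y), n = length(y),
         errors = length(y) - max(dist), dist = as.vector(dist), classes = names(dist))
  }
}

# upper confidence limit of the binomial error rate (exact form of the
# pessimistic estimate used by confidence-bound pruning)
upper_error <- function(errors, n, cf) {
  if (n == 0) return(0)
  if (errors >= n) return(1)
  stats::qbeta(1 - cf, errors + 1, n - errors)
}

subtree_pessimistic <- function(node, cf) {
  if (node$type == "leaf") return(node$n * upper_error(node$errors, node$n, cf))
  sum(vapply(node$children, subtree_pessimistic, numeric(1), cf = cf))
}

prune_node <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$children <- lapply(node$children, prune_node, cf = cf)
  as_leaf_err <- node$n * upper_error(node$errors, node$n, cf)
  subtree_err <- subtree_pessimistic(node, cf)
  if (as_leaf_err <= subtree_err + 1e-9) {
    return(list(type = "leaf", label = node$label, dist = node$dist,
                classes = node$classes, n = node$n, errors = node$errors))
  }
  node
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(vapply(node$children, tree_depth, integer(1)))
}

tree_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  sum(vapply(node$children, tree_leaves, integer(1)))
}

#' Grow a gain-ratio decision tree with pessimistic pruning
#'
#' A C4.5-style recursive partitioner for applicability metadata: continuous
#' features are split in two at the midpoint between sorted distinct values
#' that maximizes gain ratio, categorical features split multiway over their
#' observed levels, and growth stops at purity or the `min_leaf` floor. The
#' grown tree is then pruned bottom-up: a subtree is collapsed to a leaf
#' whenever the leaf's pessimistic error estimate — the binomial
#' upper-confidence error at confidence `cf` — does not exceed the subtree's.
#' A single-class input yields a single leaf.
#'
#' @param data Data frame of features plus a categorical target column.
#' @param target Name of the target column.
#' @param min_leaf Minimum cases in each branch of a split.
#' @param cf Pruning confidence (smaller prunes harder).
#' @param prune Set to `FALSE` to keep the unpruned tree.
#' @return An object of class `c45_tree`.
#' @export
build_c45_tree <- function(data, target = "target", min_leaf = 2L, cf = 0.25,
                           prune = TRUE) {
  stopifnot(target %in% names(data), min_leaf >= 1L, cf > 0, cf < 1)
  y <- factor(data[[target]])
  X <- as.data.frame(data[setdiff(names(data), target)])
  root <- grow_tree(X, y, as.integer(min_leaf), 1L)
  if (prune) root <- prune_node(root, cf)
  structure(list(root = root, target = target,
                 feature_names = names(X), classes = levels(y),
                 min_leaf = as.integer(min_leaf), cf = cf),
            class = "c45_tree")
}

descend <- function(node, row) {
  while (node$type == "split") {
    v <- row[[node$feature]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      stop("prediction needs feature '", node$feature, "', which is missing", call. = FALSE)
    }
    if (node$kind == "numeric") {
      node <- if (v <= node$threshold) node$children[["<="]] else node$children[[">"]]
    } else {
      child <- node$children[[as.character(v)]]
      if (is.null(child)) {
        # unseen level: follow the most populous branch
        sizes <- vapply(node$children, `[[`, numeric(1), "n")
        child <- node$children[[which.max(sizes)]]
      }
      node <- child
    }
  }
  node$label
}

#' Predict labels from a gain-ratio tree
#'
#' Deterministic root-to-leaf descent; each leaf returns its majority label.
#' A missing tested feature is an error naming the feature; an unseen
#' categorical level follows the most populous branch.
#'
#' @param tree A `c45_tree`.
#' @param newdata Data frame (or one-row metafeature tibble) with the
#'   features the tree tests.
#' @return Character vector of predicted labels.
#' @export
predict_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "c45_tree"))
  vapply(seq_len(nrow(newdata)), function(i) descend(tree$root, newdata[i, , drop = FALSE]),
         character(1))
}

#' @export
predict.c45_tree <- function(object, newdata, ...) predict_tree(object, newdata)

format_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf") {
    return(sprintf("%s-> %s (n=%d, err=%d)", pad, node$label, node$n, node$errors))
  }
  out <- character()
  if (node$kind == "numeric") {
    for (side in c("<=", ">")) {
      out <- c(out, sprintf("%s%s %s %.6g", pad, node$feature, side, node$threshold),
               format_node(node$children[[side]], indent + 1L))
    }
  } else {
    for (v in names(node$children)) {
      out <- c(out, sprintf("%s%s = %s", pad, node$feature, v),
               format_node(node$children[[v]], indent + 1L))
    }
  }
  out
}

#' @export
print.c45_tree <- function(x, ...) {
  cat("<c45_tree> ", tree_leaves(x$root), " leaves, depth ", tree_depth(x$root), "\n", sep = "")
  cat(paste(format_node(x$root, 0L), collapse = "\n"), "\n")
  invisible(x)
}

collect_nodes <- function(node, id = 1L, parent = NA_integer_) {
  is_split <- node$type == "split"
  self <- tibble::tibble(
    node_id = id, parent = parent, type = node$type,
    feature = if (is_split) node$feature else NA_character_,
    threshold = if (is_split && node$kind == "numeric") node$threshold else NA_real_,
    label = node$label %||% NA_character_, n = node$n, errors = node$errors
  )
  if (!is_split) return(self)
  kids <- list(); next_id <- id + 1L
  for (ch in node$children) {
    sub <- collect_nodes(ch, next_id, id)
    kids[[length(kids) + 1L]] <- sub
    next_id <- max(sub$node_id) + 1L
  }
  dplyr::bind_rows(self, kids)
}

#' Tidy a gain-ratio tree
#' @param x A `c45_tree`.
#' @param ... Ignored.
#' @return One row per node: id, parent, split feature/threshold, leaf label,
#'   case count, training errors.
#' @export
tidy.c45_tree <- function(x, ...) collect_nodes(x$root)

#' One-row summary of a gain-ratio tree
#' @param x A `c45_tree`.
#' @param ... Ignored.
#' @return Tibble with `depth`, `leaf_count`, `n`, and training accuracy.
#' @export
glance.c45_tree <- function(x, ...) {
  errs <- sum(tidy(x)$errors[tidy(x)$type == "leaf"])
  tibble::tibble(depth = tree_depth(x$root), leaf_count = tree_leaves(x$root),
                 n = x$root$n, train_accuracy = 1 - errs / x$root$n)
}

#' Stratified k-fold cross-validation of a meta-learner
#'
#' Shuffles within classes under the given seed, splits into `k` stratified
#' folds, trains the chosen learner on each training part and scores held-out
#' accuracy. `"tree"` uses [build_c45_tree()]; `"stepwise"` uses
#' [stepwise_select()] as a linear probability classifier on a binary target
#' (predicted recommendation when the fitted value exceeds 0.5). A fold whose
#' training part lacks one of the classes is skipped with a warning.
#'
#' @param data Data frame of features plus target column.
#' @param target Name of the categorical target column (binary for
#'   `"stepwise"`).
#' @param learner `"tree"` or `"stepwise"`.
#' @param k Number of folds (`k = n` gives leave-one-out).
#' @param seed Integer seed for the fold assignment.
#' @param ... Passed to the learner.
#' @return Mean held-out accuracy (fraction), with per-fold accuracies in the
#'   `folds` attribute.
#' @export
cross_validate <- function(data, target = "target", learner = c("tree", "stepwise"),
                           k = 10L, seed = 1L, ...) {
  learner <- match.arg(learner)
  y <- factor(data[[target]])
  n <- length(y)
  stopifnot(n >= k, k >= 2L)
  set.seed(seed)
  fold <- integer(n)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  accs <- vapply(seq_len(k), function(f) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    if (!nrow(te)) return(NA_real_)
    if (length(unique(tr[[target]])) < length(levels(y))) {
      warning("fold ", f, " skipped: a class is absent from the training part", call. = FALSE)
      return(NA_real_)
    }
    pred <- if (learner == "tree") {
      predict_tree(build_c45_tree(tr, target = target, ...), te)
    } else {
      lev <- levels(y)
      if (length(lev) != 2L) stop("stepwise classifier needs a binary target", call. = FALSE)
      tr2 <- tr; tr2[[target]] <- as.numeric(factor(tr[[target]], levels = lev)) - 1
      fit <- stepwise_select(tr2, target = target, ...)
      Xte <- expand_features(te, setdiff(names(te), target))
      missing_cols <- setdiff(fit$selected_features, names(Xte))
      for (mc in missing_cols) Xte[[mc]] <- 0
      p <- stats::predict(fit$fit, newdata = Xte)
      lev[(p > 0.5) + 1L]
    }
    mean(pred == as.character(te[[target]]))
  }, numeric(1))
  out <- mean(accs, na.rm = TRUE)
  attr(out, "folds") <- accs
  out
}
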