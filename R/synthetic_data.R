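#' Specification for a synthetic base dataset
#'
#' Describes a UCI-style classification table with controllable metafeature
#' structure: class priors drawn from a symmetric Dirichlet, per-class
#' Gaussian continuous attributes with a tunable mean offset and a
#' compound-symmetry correlation target, discrete/binary attributes whose
#' class dependence interpolates between independence (0) and determinism
#' (1), and an MCAR missingness mask.
#'
#' @param n_rows Sample size.
#' @param n_continuous,n_discrete,n_binary Attribute counts (at least one in
#'   total). Discrete attributes have 4 levels, binary 2.
#' @param n_classes Number of classes (>= 2).
#' @param class_prior_concentration Dirichlet concentration; large values
#'   give balanced priors.
#' @param class_separation Distance scale between class means of continuous
#'   attributes (0 = uninformative).
#' @param attribute_correlation Target mean absolute pairwise correlation of
#'   continuous attributes, in `[0, 1)`.
#' @param attribute_class_dependence Probability that a discrete attribute
#'   cell copies its class-determined level instead of a uniform draw; in
#'   `[0, 1]` and monotone in the attribute-class mutual information.
#' @param missing_rate MCAR missingness fraction of attribute cells.
#' @param domain Domain tag.
#' @param seed Integer seed.
#' @return A `base_dataset_spec` list.
#' @export
base_dataset_spec <- function(n_rows = 200L, n_continuous = 3L, n_discrete = 2L,
                              n_binary = 1L, n_classes = 2L,
                              class_prior_concentration = 10,
                              class_separation = 2,
                              attribute_correlation = 0,
                              attribute_class_dependence = 0.5,
                              missing_rate = 0, domain = "general", seed = 1L) {
  stopifnot(n_rows >= 1L, n_continuous >= 0L, n_discrete >= 0L, n_binary >= 0L,
            n_continuous + n_discrete + n_binary >= 1L, n_classes >= 2L,
            class_prior_concentration > 0, class_separation >= 0,
            attribute_correlation >= 0, attribute_correlation < 1,
            attribute_class_dependence >= 0, attribute_class_dependence <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "base_dataset_spec")
}

#' Generate a synthetic base dataset
#'
#' Draws a classification table from a [base_dataset_spec()]; the generation
#' parameters are stored on the result for ground-truth checks. Reproducible
#' from (spec, seed).
#'
#' @param spec A `base_dataset_spec`.
#' @param name Dataset name.
#' @return An `algsel_dataset` with a `generator_spec` attribute.
#' @export
generate_base_dataset <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "base_dataset_spec"))
  set.seed(spec$seed)
  k <- spec$n_classes
  priors <- rgamma(k, shape = spec$class_prior_concentration)
  priors <- priors / sum(priors)
  cls <- sample.int(k, spec$n_rows, replace = TRUE, prob = priors)
  for (try in 1:20) {
    if (length(unique(cls)) >= 2L) break
    cls <- sample.int(k, spec$n_rows, replace = TRUE, prob = priors)
  }
  if (length(unique(cls)) < 2L) stop("could not realize two classes at this sample size", call. = FALSE)
  cols <- list(); kinds <- character()
  if (spec$n_continuous > 0L) {
    rho <- spec$attribute_correlation
    mu <- matrix(stats::rnorm(k * spec$n_continuous), k, spec$n_continuous) *
      spec$class_separation
    common <- stats::rnorm(spec$n_rows)
    for (j in seq_len(spec$n_continuous)) {
      eps <- sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(spec$n_rows)
      nm <- sprintf("x%02d", j)
      cols[[nm]] <- mu[cls, j] + eps
      kinds[nm] <- "continuous"
    }
  }
  gen_discrete <- function(levels_n, prefix, count) {
    for (j in seq_len(count)) {
      perm <- sample.int(levels_n)
      determined <- perm[(cls - 1L) %% levels_n + 1L]
      uniform <- sample.int(levels_n, spec$n_rows, replace = TRUE)
      use_det <- stats::runif(spec$n_rows) < spec$attribute_class_dependence
      nm <- sprintf("%s%02d", prefix, j)
      cols[[nm]] <<- paste0("L", ifelse(use_det, determined, uniform))
      kinds[nm] <<- if (levels_n == 2L) "binary" else "discrete"
    }
  }
  gen_discrete(4L, "d", spec$n_discrete)
  gen_discrete(2L, "b", spec$n_binary)
  df <- tibble::as_tibble(cols)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(nrow(df) * ncol(df)) < spec$missing_rate,
                   nrow(df), ncol(df))
    for (j in seq_along(df)) df[[j]][mask[, j]] <- NA
  }
  df$class <- paste0("C", cls)
  out <- as_dataset(df, class = "class", kinds = kinds, domain = spec$domain, name = name)
  attr(out, "generator_spec") <- spec
  out
}

#' Generate a meta-dataset with a planted applicability rule
#'
#' Samples metafeature vectors from plausible ranges of each indicator
#' (counts log-uniform, ratios respecting the class-frequency orderings,
#' entropies consistent with `E_C >= MME_CV` and `ME_V >= MME_CV`), labels
#' each vector by a planted predicate — a conjunction of
#' `(feature, comparator, threshold)` conditions — and flips each label with
#' probability `label_noise`. This is the test bed for the meta-learners:
#' recovery of the planted rule is checkable because the truth is known.
#'
#' @param rule List of conditions, each `list(feature, op, threshold)` with
#'   `op` one of `<, <=, >, >=, ==`; the label is `"Y"` when all hold.
#' @param n Number of metafeature vectors.
#' @param label_noise Label flip probability.
#' @param seed Integer seed.
#' @return Tibble of the 26 indicators plus `field_label` and a `target`
#'   column with labels `"Y"`/`"No"`.
#' @export
generate_meta_dataset <- function(rule, n = 400L, label_noise = 0, seed = 1L) {
  stopifnot(n >= 1L, label_noise >= 0, label_noise <= 1)
  set.seed(seed)
  n_class <- sample(2:10, n, replace = TRUE)
  r_least <- stats::runif(n, 0.01, 1 / n_class)
  r_largest <- stats::runif(n, 1 / n_class, pmax(1 / n_class, 1 - (n_class - 1) * r_least))
  r_discrete <- stats::runif(n)
  e_c <- stats::runif(n, 0.1, log2(n_class))
  mme_cv <- stats::runif(n, 0.01, e_c)
  me_v <- mme_cv + stats::runif(n, 0, 3)
  mf <- tibble::tibble(
    P = sample(2:100, n, replace = TRUE),
    N = round(exp(stats::runif(n, log(50), log(20000)))),
    N_class = n_class,
    R_largest = r_largest, R_least = r_least,
    R_binary = stats::runif(n) * r_discrete,
    R_discrete = r_discrete, R_continuous = 1 - r_discrete,
    R_missing = stats::runif(n, 0, 0.3),
    Geomean = exp(stats::runif(n, -2, 3)),
    Harmean = exp(stats::runif(n, -2, 3)),
    Trimean = stats::rnorm(n, 2, 3),
    Prctile = stats::rnorm(n, 5, 4),
    MAD = exp(stats::runif(n, -2, 2)),
    Var = exp(stats::runif(n, -2, 4)),
    Std = exp(stats::runif(n, -1, 2)),
    MAr = stats::runif(n),
    IQR = exp(stats::runif(n, -2, 2)),
    D = exp(stats::runif(n, -2, 2)),
    Skewness = stats::rnorm(n, 0, 1.5),
    Kurtosis = stats::runif(n, 1.5, 10),
    ME_V = me_v, E_C = e_c, MME_CV = mme_cv,
    ENV = e_c / mme_cv,
    NSR = (me_v - mme_cv) / mme_cv,
    field_label = sample(c("medical", "biology", "general"), n, replace = TRUE)
  )
  unknown <- setdiff(vapply(rule, `[[`, character(1), "feature"), names(mf))
  if (length(unknown)) {
    stop("rule references unknown metafeature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  holds <- rep(TRUE, n)
  for (cn in rule) holds <- holds & apply_op(mf[[cn$feature]], cn$op, cn$threshold)
  flip <- stats::runif(n) < label_noise
  mf$target <- ifelse(xor(holds, flip), "Y", "No")
  mf
}

read_fixture <- function(file) {
  readr::read_csv(system.file("extdata", file, package = "algsel"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Published completion/failure counts by algorithm and category
#'
#' Transcription of the original study's modeling-completion summary over
#' its 293 benchmark sub-datasets: completed and failed counts per dataset
#' category plus the total-failed column for each of the eight algorithms.
#'
#' @return Tibble with one row per algorithm.
#' @export
fixture_table1 <- function() read_fixture("table1_counts.csv")

#' Published label-by-domain contingency table for LR on discrete datasets
#'
#' The 3x3 recommendation table (rows medical/biology/general, columns
#' Y/M/No; n = 34) used as the worked example of the R-by-C chi-square.
#'
#' @return A `contingency_table`.
#' @export
fixture_table2 <- function() {
  df <- read_fixture("table2_contingency.csv")
  counts <- as.matrix(df[, c("Y", "M", "No")])
  rownames(counts) <- df$domain
  new_contingency(counts)
}

#' Published per-algorithm chi-square values and verdicts
#'
#' The eight chi-square statistics of the domain-difference analysis on
#' discrete datasets, with the printed between-group difference verdicts.
#'
#' @return Tibble with `algorithm`, `chi2`, `different`.
#' @export
fixture_table3 <- function() read_fixture("table3_chisq.csv")
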