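#' Shannon entropy of a count vector
#'
#' @param counts Nonnegative counts over categories; at least one positive.
#' @param base Logarithm base (> 1); base 2 gives bits.
#' @return Entropy, between 0 and `log(k, base)` for `k` categories.
#' @examples
#' shannon_entropy(c(5, 5, 5, 5)) # 2 bits
#' @export
shannon_entropy <- function(counts, base = 2) {
  stopifnot(base > 1, all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / n
  -sum(p * log(p, base = base))
}

#' Mutual information of two discrete vectors
#'
#' Computed from the joint count table as `H(X) + H(Y) - H(X, Y)` and clamped
#' at zero against round-off.
#'
#' @param x,y Equal-length vectors treated as categorical.
#' @param base Logarithm base (> 1).
#' @return Mutual information, `>= 0` and `<= min(H(X), H(Y))`.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  stopifnot(length(x) >= 1L)
  joint <- table(x, y)
  hx <- shannon_entropy(rowSums(joint), base)
  hy <- shannon_entropy(colSums(joint), base)
  hxy <- shannon_entropy(as.vector(joint), base)
  max(0, hx + hy - hxy)
}

#' Equal-width discretization
#'
#' Bins span `[min, max]` in equal widths; the maximum value falls in the
#' last bin and a constant vector occupies a single bin. Used to turn
#' continuous attributes into categories before entropy and mutual
#' information estimation.
#'
#' @param values Numeric vector with at least one finite value.
#' @param n_bins Number of bins (>= 1).
#' @return Integer bin indices in `1..n_bins` (`NA` stays `NA`).
#' @export
discretize_equal_width <- function(values, n_bins) {
  stopifnot(n_bins >= 1L)
  finite <- values[is.finite(values)]
  if (!length(finite)) stop("no finite values to discretize", call. = FALSE)
  lo <- min(finite); hi <- max(finite)
  if (hi == lo) return(ifelse(is.na(values), NA_integer_, 1L))
  idx <- floor((values - lo) / (hi - lo) * n_bins) + 1L
  as.integer(pmin(idx, n_bins))
}

sturges_bins <- function(n) max(2L, as.integer(ceiling(log2(max(n, 1)))) + 1L)

#' Simple metafeatures
#'
#' The counting indicators: number of attributes `P`, sample size `N`, number
#' of classes `N_class`, largest/least class frequency ratios, the binary /
#' discrete / continuous attribute-kind ratios (binary counts as discrete, so
#' `R_discrete + R_continuous = 1`), and the raw missing-value ratio recorded
#' before preprocessing.
#'
#' @param data A preprocessed `algsel_dataset`.
#' @return One-row tibble.
#' @export
simple_metafeatures <- function(data) {
  stopifnot(inherits(data, "algsel_dataset"))
  kinds <- dataset_kinds(data)
  cls <- table(data[[dataset_class(data)]])
  cls <- cls[cls > 0]
  tibble::tibble(
    P = length(kinds),
    N = nrow(data),
    N_class = length(cls),
    R_largest = max(cls) / sum(cls),
    R_least = min(cls) / sum(cls),
    R_binary = mean(kinds == "binary"),
    R_discrete = mean(kinds %in% c("binary", "discrete")),
    R_continuous = mean(kinds == "continuous"),
    R_missing = attr(data, "raw_missing_ratio")
  )
}

moment_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

#' Statistical metafeatures
#'
#' Per continuous attribute: geometric mean, harmonic mean, trimmed mean,
#' upper percentile, mean absolute deviation about the mean, sample variance
#' (n-1), standard deviation, interquartile range, index of dispersion
#' (variance/mean), skewness (biased g1) and non-excess kurtosis (normal = 3);
#' each aggregated by the arithmetic mean over eligible attributes. `MAr` is
#' the mean absolute Pearson correlation over unordered pairs of continuous
#' attributes. Attributes containing non-positive values are excluded from
#' the geometric and harmonic means, attributes with zero mean from the
#' dispersion index; exclusions and the all-discrete case are recorded as
#' flags rather than errors, with the affected indicators reported as 0.
#'
#' @param data A preprocessed `algsel_dataset`.
#' @param trim Tail fraction trimmed from each side for the trimmed mean.
#' @param percentile Probability of the reported percentile.
#' @return One-row tibble with a `flags` attribute (character vector of
#'   eligibility notes).
#' @export
statistical_metafeatures <- function(data, trim = 0.10, percentile = 0.90) {
  stopifnot(inherits(data, "algsel_dataset"))
  kinds <- dataset_kinds(data)
  cont <- names(kinds)[kinds == "continuous"]
  flags <- character()
  zero_row <- tibble::tibble(
    Geomean = 0, Harmean = 0, Trimean = 0, Prctile = 0, MAD = 0, Var = 0,
    Std = 0, MAr = 0, IQR = 0, D = 0, Skewness = 0, Kurtosis = 0
  )
  if (!length(cont)) {
    attr(zero_row, "flags") <- "no continuous attributes: statistical indicators set to 0"
    return(zero_row)
  }
  cols <- lapply(data[cont], function(col) as.numeric(col))
  agg <- function(vals) if (length(vals)) mean(vals) else 0
  positive <- vapply(cols, function(x) all(x > 0), logical(1))
  if (any(!positive)) {
    flags <- c(flags, paste0(
      "non-positive values: excluded from Geomean/Harmean: ",
      paste(cont[!positive], collapse = ", ")
    ))
  }
  nonzero_mean <- vapply(cols, function(x) mean(x) != 0, logical(1))
  if (any(!nonzero_mean)) {
    flags <- c(flags, paste0(
      "zero mean: excluded from dispersion index: ",
      paste(cont[!nonzero_mean], collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    Geomean = agg(vapply(cols[positive], function(x) exp(mean(log(x))), numeric(1))),
    Harmean = agg(vapply(cols[positive], function(x) 1 / mean(1 / x), numeric(1))),
    Trimean = agg(vapply(cols, function(x) mean(x, trim = trim), numeric(1))),
    Prctile = agg(vapply(cols, function(x) unname(stats::quantile(x, percentile)), numeric(1))),
    MAD = agg(vapply(cols, function(x) mean(abs(x - mean(x))), numeric(1))),
    Var = agg(vapply(cols, stats::var, numeric(1))),
    Std = agg(vapply(cols, stats::sd, numeric(1))),
    MAr = 0,
    IQR = agg(vapply(cols, stats::IQR, numeric(1))),
    D = agg(vapply(cols[nonzero_mean], function(x) stats::var(x) / mean(x), numeric(1))),
    Skewness = agg(vapply(cols, moment_skewness, numeric(1))),
    Kurtosis = agg(vapply(cols, moment_kurtosis, numeric(1)))
  )
  if (length(cont) >= 2L) {
    cm <- suppressWarnings(stats::cor(as.data.frame(cols)))
    r <- abs(cm[upper.tri(cm)])
    r[is.na(r)] <- 0  # constant attribute: correlation undefined, counted as 0
    out$MAr <- mean(r)
  } else {
    flags <- c(flags, "fewer than 2 continuous attributes: MAr set to 0")
  }
  attr(out, "flags") <- flags
  out
}

#' Information-theoretic metafeatures
#'
#' Class entropy `E_C`, mean attribute entropy `ME_V`, mean attribute-class
#' mutual information `MME_CV`, the equivalent number of variables
#' `ENV = E_C / MME_CV` and the noise-signal ratio
#' `NSR = (ME_V - MME_CV) / MME_CV`. Continuous attributes are discretized
#' with equal-width bins (Sturges' rule by default) before the entropies are
#' taken, which keeps every entropy nonnegative and hence `ENV >= 1` and
#' `NSR >= 0`. An alternative `estimator = "differential"` replaces the
#' histogram entropy of continuous attributes in `ME_V` by the Gaussian
#' differential entropy `0.5 * log(2 * pi * e * var)`, which can be negative
#' for tightly concentrated attributes and thus permits negative `NSR`
#' values. With `MME_CV = 0` the two ratios are undefined; they are reported
#' as `Inf` with a flag.
#'
#' @param data A preprocessed `algsel_dataset`.
#' @param n_bins Bin count for continuous attributes; default Sturges.
#' @param base Entropy logarithm base.
#' @param estimator `"histogram"` (default) or `"differential"` for the
#'   continuous part of `ME_V`.
#' @return One-row tibble with a `flags` attribute.
#' @export
information_metafeatures <- function(data, n_bins = NULL, base = 2,
                                     estimator = c("histogram", "differential")) {
  stopifnot(inherits(data, "algsel_dataset"))
  estimator <- match.arg(estimator)
  kinds <- dataset_kinds(data)
  y <- data[[dataset_class(data)]]
  n_bins <- n_bins %||% sturges_bins(nrow(data))
  e_c <- shannon_entropy(as.vector(table(y)), base)
  flags <- character()
  per_attr <- purrr::map(names(kinds), function(nm) {
    col <- data[[nm]]
    if (kinds[[nm]] == "continuous") {
      binned <- discretize_equal_width(as.numeric(col), n_bins)
      h <- if (estimator == "differential") {
        v <- stats::var(as.numeric(col))
        if (v > 0) 0.5 * log(2 * pi * exp(1) * v, base = base) else 0
      } else {
        shannon_entropy(as.vector(table(binned)), base)
      }
      list(h = h, mi = mutual_information(binned, y, base))
    } else {
      list(h = shannon_entropy(as.vector(table(col)), base),
           mi = mutual_information(col, y, base))
    }
  })
  me_v <- mean(vapply(per_attr, `[[`, numeric(1), "h"))
  mme_cv <- mean(vapply(per_attr, `[[`, numeric(1), "mi"))
  if (mme_cv > 0) {
    env <- e_c / mme_cv
    nsr <- (me_v - mme_cv) / mme_cv
  } else {
    flags <- c(flags, "MME_CV = 0: ENV and NSR undefined, reported as Inf")
    env <- Inf
    nsr <- Inf
  }
  out <- tibble::tibble(ME_V = me_v, E_C = e_c, MME_CV = mme_cv, ENV = env, NSR = nsr)
  attr(out, "flags") <- flags
  out
}

#' The canonical metafeature column order
#' @return Character vector of the 26 indicator names followed by
#'   `field_label`.
#' @export
metafeature_names <- function() {
  c("P", "N", "N_class", "R_largest", "R_least", "R_binary", "R_discrete",
    "R_continuous", "R_missing",
    "Geomean", "Harmean", "Trimean", "Prctile", "MAD", "Var", "Std", "MAr",
    "IQR", "D", "Skewness", "Kurtosis",
    "ME_V", "E_C", "MME_CV", "ENV", "NSR", "field_label")
}

#' Characterize a dataset with the 26 indicators
#'
#' Unions the simple, statistical and information-theoretic metafeatures and
#' appends the dataset's domain tag as `field_label`, giving the full
#' characterization vector used both by the published formula bank and by the
#' meta-learners. Deterministic given the dataset and the binning/base
#' settings.
#'
#' @inheritParams information_metafeatures
#' @inheritParams statistical_metafeatures
#' @return One-row tibble with columns in [metafeature_names()] order and a
#'   `flags` attribute collecting eligibility notes.
#' @examples
#' d <- preprocess(as_dataset(iris, class = "Species", domain = "biology"))
#' characterize(d)
#' @export
characterize <- function(data, n_bins = NULL, base = 2, trim = 0.10,
                         percentile = 0.90, estimator = "histogram") {
  simple <- simple_metafeatures(data)
  stat <- statistical_metafeatures(data, trim = trim, percentile = percentile)
  info <- information_metafeatures(data, n_bins = n_bins, base = base,
                                   estimator = estimator)
  out <- dplyr::bind_cols(simple, stat, info)
  out$field_label <- dataset_domain(data)
  out <- out[, metafeature_names()]
  attr(out, "flags") <- c(attr(stat, "flags"), attr(info, "flags"))
  attr(out, "entropy_base") <- base
  out
}
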