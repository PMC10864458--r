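# shared fixtures, all built in code

# small mixed dataset with known structure
toy_mixed <- function(n = 30L, seed = 42L) {
  set.seed(seed)
  cls <- rep(c("a", "b"), length.out = n)
  as_dataset(
    tibble::tibble(
      num1 = rnorm(n) + 2 * (cls == "a"),
      num2 = runif(n),
      cat1 = sample(c("u", "v", "w"), n, replace = TRUE),
      bin1 = sample(c("y", "n"), n, replace = TRUE),
      outcome = cls
    ),
    class = "outcome",
    kinds = c(num1 = "continuous", num2 = "continuous",
              cat1 = "discrete", bin1 = "binary"),
    domain = "medical", name = "toy"
  )
}

# a cleanly separable two-Gaussian dataset for benchmark sanity checks
separable_dataset <- function(n = 240L, seed = 7L, separation = 4) {
  generate_base_dataset(
    base_dataset_spec(n_rows = n, n_continuous = 3L, n_discrete = 1L,
                      n_binary = 1L, n_classes = 2L,
                      class_separation = separation,
                      attribute_class_dependence = 0.8, seed = seed,
                      domain = "medical"),
    name = "separable"
  )
}

# independent feature draws sized so every term of the target formula is
# identifiable at n = 500 under noise sd 0.1 (a parameter-recovery design,
# not the correlated meta-dataset sampler)
recovery_metadata <- function(n = 500L, seed = 1L, noise_sd = 0.1) {
  set.seed(seed)
  df <- tibble::tibble(
    N = runif(n, 100, 30000),
    N_class = sample(2:10, n, replace = TRUE),
    ENV = runif(n, 1, 60),
    Skewness = rnorm(n),
    MAr = runif(n),
    Kurtosis = runif(n, 1.5, 9)
  )
  df$target <- -1.419 + 0.00007 * df$N + 0.0526 * df$N_class + 0.0074 * df$ENV +
    rnorm(n, sd = noise_sd)
  df
}

planted_rule_p15 <- function() list(list(feature = "P", op = ">", threshold = 15))

# entropy by direct summation, independent of the package implementation
entropy_oracle <- function(counts, base = 2) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

# mutual information by explicit summation over the joint table
mi_oracle <- function(x, y, base = 2) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  total <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0) {
      total <- total + unname(joint[i, j] * log(joint[i, j] / (px[i] * py[j]), base = base))
    }
  }
  total
}

# classical Pearson statistic as the independent chi-square oracle
pearson_oracle <- function(counts) {
  n <- sum(counts)
  e <- outer(rowSums(counts), colSums(counts)) / n
  sum((counts - e)^2 / e)
}

random_contingency <- function(rmax = 4L, cmax = 4L) {
  repeat {
    r <- sample(2:rmax, 1); c <- sample(2:cmax, 1)
    m <- matrix(rpois(r * c, lambda = 5), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
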