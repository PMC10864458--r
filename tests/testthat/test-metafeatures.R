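test_that("entropy matches direct summation and respects its bounds", {
  expect_equal(shannon_entropy(c(5, 5, 5, 5)), 2.0)
  expect_equal(shannon_entropy(c(10)), 0.0)
  expect_error(shannon_entropy(c(0, 0)), "zero")
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    counts <- rpois(k, lambda = 6) + 1
    h <- shannon_entropy(counts)
    expect_equal(h, entropy_oracle(counts), tolerance = 1e-12)
    expect_lte(h, log2(k) + 1e-12)
    expect_gte(h, 0)
  }
})

test_that("mutual information matches the joint-table oracle and its bounds", {
  x <- rep(1:4, each = 5)
  expect_equal(mutual_information(x, x), 2.0)
  expect_equal(mutual_information(rep(1, 20), sample(1:3, 20, replace = TRUE)), 0.0)
  expect_error(mutual_information(1:3, 1:4), "length")
  set.seed(12)
  for (i in 1:20) {
    n <- 60
    x <- sample(1:4, n, replace = TRUE)
    y <- ifelse(runif(n) < 0.5, x, sample(1:3, n, replace = TRUE))
    mi <- mutual_information(x, y)
    expect_equal(mi, mi_oracle(x, y), tolerance = 1e-12)
    hx <- shannon_entropy(as.vector(table(x)))
    hy <- shannon_entropy(as.vector(table(y)))
    expect_lte(mi, min(hx, hy) + 1e-9)
    expect_gte(mi, 0)
  }
})

test_that("equal-width binning covers the range and conserves counts", {
  expect_equal(discretize_equal_width(c(0, 1, 2, 3), 2), c(1L, 1L, 2L, 2L))
  expect_equal(unique(discretize_equal_width(rep(3.5, 6), 4)), 1L)
  expect_error(discretize_equal_width(numeric(0), 3), "finite")
  set.seed(13)
  v <- rnorm(57)
  bins <- discretize_equal_width(v, 5)
  expect_equal(length(bins), 57L)
  expect_true(all(bins >= 1L & bins <= 5L))
})

test_that("simple indicators come from class frequencies and kind ratios", {
  df <- tibble::tibble(
    b = rep(c("y", "n"), 5),
    d = rep(c("u", "v", "w", "u", "v"), 2),
    x = rnorm(10),
    cls = rep(c("A", "A", "B", "B", "C"), 2)
  )
  d <- as_dataset(df, class = "cls",
                  kinds = c(b = "binary", d = "discrete", x = "continuous"),
                  domain = "medical")
  s <- simple_metafeatures(d)
  expect_equal(s$P, 3L)
  expect_equal(s$N, 10L)
  expect_equal(s$N_class, 3L)
  expect_equal(s$R_largest, 0.4)
  expect_equal(s$R_least, 0.2)
  # binary is a sub-kind of discrete
  expect_equal(s$R_binary, 1 / 3)
  expect_equal(s$R_discrete, 2 / 3)
  expect_equal(s$R_continuous, 1 / 3)
  expect_equal(s$R_discrete + s$R_continuous, 1)

  balanced <- as_dataset(tibble::tibble(x = rnorm(12), cls = rep(c("a", "b", "c"), 4)),
                         class = "cls", domain = "general")
  sb <- simple_metafeatures(balanced)
  expect_equal(sb$R_largest, sb$R_least)
  expect_equal(sb$R_largest, 1 / 3)
})

test_that("statistical indicators agree with hand arithmetic and eligibility rules", {
  d <- as_dataset(tibble::tibble(v = c(1, 2, 3, 4), cls = c("a", "b", "a", "b")),
                  class = "cls", kinds = c(v = "continuous"), domain = "general")
  s <- statistical_metafeatures(d)
  expect_equal(s$Var, 5 / 3)
  expect_equal(s$Std, sqrt(5 / 3))
  expect_equal(s$MAD, 1.0)
  expect_equal(s$Geomean, prod(1:4)^(1 / 4))
  expect_equal(s$Harmean, 4 / sum(1 / (1:4)))
  expect_equal(s$D, (5 / 3) / 2.5)

  # perfectly correlated pair
  x <- rnorm(20)
  d2 <- as_dataset(tibble::tibble(a = x, b = 2 * x + 1, cls = rep(c("p", "q"), 10)),
                   class = "cls",
                   kinds = c(a = "continuous", b = "continuous"), domain = "general")
  expect_equal(statistical_metafeatures(d2)$MAr, 1.0)

  # non-positive attribute excluded from Geomean/Harmean with a flag
  d3 <- as_dataset(tibble::tibble(pos = c(1, 2, 3, 4), neg = c(-1, 2, 3, 4),
                                  cls = c("a", "b", "a", "b")),
                   class = "cls",
                   kinds = c(pos = "continuous", neg = "continuous"), domain = "general")
  s3 <- statistical_metafeatures(d3)
  expect_equal(s3$Geomean, prod(1:4)^(1 / 4))  # only the positive attribute
  expect_match(paste(attr(s3, "flags"), collapse = " "), "neg")

  # all-discrete dataset: zeros plus a flag
  d4 <- as_dataset(tibble::tibble(g = rep(c("u", "v"), 5), cls = rep(c("a", "b"), 5)),
                   class = "cls", kinds = c(g = "binary"), domain = "general")
  s4 <- statistical_metafeatures(d4)
  expect_true(all(unlist(s4) == 0))
  expect_match(attr(s4, "flags"), "no continuous")
})

test_that("information indicators follow their defining ratios", {
  # attribute identical to the class: MI = H(class), so alone ENV = 1, NSR = 0
  cls <- rep(c("a", "b", "c"), each = 4)
  d <- as_dataset(tibble::tibble(copy = cls, cls = cls), class = "cls",
                  kinds = c(copy = "discrete"), domain = "general")
  i <- information_metafeatures(d)
  expect_equal(i$E_C, log2(3))
  expect_equal(i$MME_CV, log2(3))
  expect_equal(i$ENV, 1.0)
  expect_equal(i$NSR, 0.0)

  # stated ratio definitions on a two-attribute dataset, via the oracle
  set.seed(14)
  x1 <- sample(c("u", "v"), 40, replace = TRUE)
  x2 <- sample(c("p", "q", "r"), 40, replace = TRUE)
  y <- ifelse(runif(40) < 0.6, ifelse(x1 == "u", "a", "b"), sample(c("a", "b"), 40, TRUE))
  d2 <- as_dataset(tibble::tibble(x1 = x1, x2 = x2, cls = y), class = "cls",
                   kinds = c(x1 = "binary", x2 = "discrete"), domain = "general")
  i2 <- information_metafeatures(d2)
  me_v <- mean(c(entropy_oracle(table(x1)), entropy_oracle(table(x2))))
  mme <- mean(c(mi_oracle(x1, y), mi_oracle(x2, y)))
  expect_equal(i2$ME_V, me_v, tolerance = 1e-12)
  expect_equal(i2$MME_CV, mme, tolerance = 1e-12)
  expect_equal(i2$ENV, i2$E_C / i2$MME_CV)
  expect_equal(i2$NSR, (i2$ME_V - i2$MME_CV) / i2$MME_CV)

  # uninformative constant attribute: MME_CV = 0 flagged, ratios Inf
  d3 <- as_dataset(tibble::tibble(k = rep("z", 10), cls = rep(c("a", "b"), 5)),
                   class = "cls", kinds = c(k = "discrete"), domain = "general")
  i3 <- information_metafeatures(d3)
  expect_equal(i3$ENV, Inf)
  expect_match(attr(i3, "flags"), "undefined")
})

test_that("characterization has the full schema, is deterministic, scales as expected", {
  d <- preprocess(toy_mixed())
  mf <- characterize(d)
  expect_equal(names(mf), metafeature_names())
  expect_equal(ncol(mf), 27L)
  expect_identical(mf, characterize(d))

  # scaling a continuous attribute up increases aggregated Var but leaves the
  # discrete information indicators untouched
  scaled_tbl <- tibble::as_tibble(as.data.frame(d))
  scaled_tbl$num1 <- scaled_tbl$num1 * 10
  scaled <- as_dataset(scaled_tbl, class = "outcome", kinds = dataset_kinds(d),
                       domain = "medical")
  mfs <- characterize(scaled)
  expect_gt(mfs$Var, mf$Var)
  expect_equal(mfs$E_C, mf$E_C)
  expect_equal(mfs[c("R_binary", "R_discrete", "R_continuous")],
               mf[c("R_binary", "R_discrete", "R_continuous")])
})

test_that("differential-entropy mode can produce negative noise-signal ratios", {
  set.seed(15)
  cls <- rep(c("a", "b"), 30)
  d <- as_dataset(tibble::tibble(x = rnorm(60, sd = 1e-4), cls = cls),
                  class = "cls", kinds = c(x = "continuous"), domain = "general")
  i <- information_metafeatures(d, estimator = "differential")
  expect_lt(i$ME_V, 0)
  expect_lt(i$NSR, 0)
})
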