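test_that("delimited reading with a schema sidecar handles sentinels and schema errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c,grp", "1,2.5,x,p", "2,?,y,q", "3,4.5,,p", "4,1.0,x,q"), csv)
  schema <- list(
    columns = list(list(name = "a", kind = "discrete"),
                   list(name = "b", kind = "continuous"),
                   list(name = "c", kind = "discrete"),
                   list(name = "grp")),
    class = "grp", domain = "medical"
  )
  d <- read_dataset(csv, schema)
  expect_s3_class(d, "algsel_dataset")
  expect_equal(length(attribute_names(d)), 3L)
  expect_equal(dataset_domain(d), "medical")
  # two sentinel cells ("?" and empty) among 12 attribute cells
  expect_equal(attr(d, "raw_missing_ratio"), 2 / 12)

  bad_schema <- schema
  bad_schema$columns <- bad_schema$columns[-2]
  expect_error(read_dataset(csv, bad_schema), "does not name")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,c,grp", empty)
  expect_error(read_dataset(empty, schema), "empty")
})

test_that("ARFF attributes map to kinds (nominal to discrete, 2 levels to binary)", {
  arff <- withr::local_tempfile(fileext = ".arff")
  writeLines(c(
    "@relation toy",
    "@attribute x numeric",
    "@attribute col {red,green,blue}",
    "@attribute flag {yes,no}",
    "@attribute class {a,b}",
    "@data",
    "1.2,red,yes,a", "3.4,blue,no,b", "2.2,green,yes,a", "0.1,red,no,b"
  ), arff)
  d <- read_arff_dataset(arff, domain = "biology")
  expect_equal(unname(dataset_kinds(d)[c("x", "col", "flag")]),
               c("continuous", "discrete", "binary"))
  expect_equal(dataset_class(d), "class")
})

test_that("kind inference distinguishes binary, discrete and continuous columns", {
  df <- data.frame(
    b = rep(c(0, 1), 10),
    txt = rep(c("u", "v", "w", "x", "y"), 4),
    cont = seq(0.1, 2, length.out = 20),
    const = rep(3, 20)
  )
  kinds <- infer_variable_kinds(df, max_discrete_cardinality = 10L)
  expect_equal(unname(kinds), c("binary", "discrete", "continuous", "discrete"))
})

test_that("sparse-attribute removal uses a strict threshold and is column-local", {
  n <- 100L
  make <- function(miss_a, miss_b) {
    a <- rnorm(n); a[seq_len(miss_a)] <- NA
    b <- rnorm(n); b[seq_len(miss_b)] <- NA
    as_dataset(tibble::tibble(a = a, b = b, cc = rnorm(n),
                              cls = rep(c("x", "y"), n / 2)),
               class = "cls", domain = "general")
  }
  d <- make(31L, 30L)
  kept <- drop_sparse_attributes(d, 0.30)
  expect_false("a" %in% names(kept))   # 31% > 30%: removed
  expect_true("b" %in% names(kept))    # exactly 30%: retained
  expect_equal(attr(kept, "provenance")$dropped_columns, "a")

  clean <- make(0L, 0L)
  expect_equal(names(drop_sparse_attributes(clean)), names(clean))

  # the decision for column a does not depend on the other columns
  d2 <- make(31L, 0L)
  d2_perm <- d2[, c("cc", "b", "a", "cls")]
  d2_perm <- as_dataset(tibble::as_tibble(d2_perm), class = "cls",
                        kinds = dataset_kinds(d2)[c("cc", "b", "a")], domain = "general")
  expect_false("a" %in% names(drop_sparse_attributes(d2_perm)))

  all_bad <- as_dataset(tibble::tibble(a = c(NA, NA, NA, 1),
                                       cls = c("x", "y", "x", "y")),
                        class = "cls", domain = "general")
  expect_error(drop_sparse_attributes(all_bad), "degenerate")
})

test_that("complete-case filtering keeps class labels aligned and errors when empty", {
  set.seed(1)
  df <- tibble::tibble(a = rnorm(10), b = rnorm(10), cls = rep(c("x", "y"), 5))
  df$a[c(2, 7)] <- NA
  d <- as_dataset(df, class = "cls", domain = "general")
  kept <- drop_incomplete_rows(d)
  expect_equal(nrow(kept), 8L)
  expect_equal(kept$cls, df$cls[-c(2, 7)])
  expect_equal(attr(kept, "provenance")$dropped_rows, c(2L, 7L))

  complete <- as_dataset(tibble::tibble(a = 1:4, cls = c("x", "y", "x", "y")),
                         class = "cls", domain = "general")
  expect_equal(nrow(drop_incomplete_rows(complete)), 4L)

  all_na <- as_dataset(tibble::tibble(a = c(NA_real_, NA_real_), cls = c("x", "y")),
                       class = "cls", domain = "general")
  expect_error(drop_incomplete_rows(all_na), "degenerate")
})

test_that("preprocessing drops sparse attributes before rows, keeps raw ratio, is idempotent", {
  n <- 20L
  a <- rnorm(n); a[1:10] <- NA          # 50% missing: attribute goes first
  b <- rnorm(n); b[1:2] <- NA           # then 2 incomplete rows go
  d <- as_dataset(tibble::tibble(a = a, b = b, cls = rep(c("x", "y"), n / 2)),
                  class = "cls", domain = "general")
  raw <- attr(d, "raw_missing_ratio")
  p <- preprocess(d)
  expect_false("a" %in% names(p))
  expect_equal(nrow(p), 18L)            # only b's 2 rows dropped, not a's 10
  expect_equal(attr(p, "raw_missing_ratio"), raw)
  expect_false(anyNA(p[attribute_names(p)]))

  p2 <- preprocess(p)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  expect_equal(nrow(p2), nrow(p))

  clean <- toy_mixed()
  pc <- preprocess(clean)
  expect_equal(as.data.frame(pc), as.data.frame(clean))
  expect_length(attr(pc, "provenance")$dropped_columns, 0L)
})

test_that("dataset category partitions by attribute kinds", {
  base <- tibble::tibble(x = rnorm(9), y = rnorm(9), z = rep(c("a", "b", "c"), 3),
                         cls = rep(c("p", "q", "p"), 3))
  all_cont <- as_dataset(base[c("x", "y", "cls")], class = "cls",
                         kinds = c(x = "continuous", y = "continuous"), domain = "general")
  all_disc <- as_dataset(base[c("z", "cls")], class = "cls",
                         kinds = c(z = "binary"), domain = "general")
  mixed <- as_dataset(base, class = "cls",
                      kinds = c(x = "continuous", y = "continuous", z = "discrete"),
                      domain = "general")
  expect_equal(dataset_category(all_cont), "continuous")
  expect_equal(dataset_category(all_disc), "discrete")
  expect_equal(dataset_category(mixed), "mixed")
  expect_length(
    unique(c(dataset_category(all_cont), dataset_category(all_disc), dataset_category(mixed))),
    3L)
})
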