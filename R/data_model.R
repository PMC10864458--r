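#' Construct a tabular classification dataset
#'
#' Wraps a data frame as the unit of characterization and benchmarking: an
#' attribute matrix with declared per-column kinds, a class column, and a
#' domain tag. Missing attribute cells are represented as `NA`; the class
#' column must be complete. The fraction of missing attribute cells at
#' construction time is recorded as the raw missing ratio, because downstream
#' preprocessing removes all missing cells and would otherwise erase the
#' information the `R_missing` indicator needs.
#'
#' @param data A data frame containing the attribute columns and the class
#'   column.
#' @param class Name of the class column. It must have no missing values and,
#'   for benchmarking, at least two distinct labels.
#' @param kinds Named character vector giving the kind of every attribute
#'   column: one of `"binary"`, `"discrete"`, `"continuous"`. If `NULL`, kinds
#'   are inferred with [infer_variable_kinds()]. Binary is treated as a
#'   sub-kind of discrete throughout, so the discrete and continuous ratios
#'   sum to one.
#' @param domain Domain tag, one of `"medical"`, `"biology"`, `"general"`.
#' @param name Dataset name used in benchmark records.
#' @return A tibble of class `algsel_dataset` carrying `class_col`, `kinds`,
#'   `domain`, `name` and `raw_missing_ratio` attributes.
#' @examples
#' d <- as_dataset(iris, class = "Species", domain = "biology")
#' dataset_category(d)
#' @export
as_dataset <- function(data, class, kinds = NULL, domain = c("general", "medical", "biology"),
                       name = "dataset") {
  stopifnot(is.data.frame(data))
  domain <- match.arg(domain)
  if (!class %in% names(data)) {
    stop("class column '", class, "' not found in data", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1L || ncol(data) < 2L) {
    stop("dataset needs at least one row and one attribute besides the class", call. = FALSE)
  }
  if (anyNA(data[[class]])) {
    stop("class column must not contain missing values", call. = FALSE)
  }
  attr_cols <- setdiff(names(data), class)
  if (is.null(kinds)) {
    kinds <- infer_variable_kinds(data[attr_cols])
  } else {
    if (is.null(names(kinds)) || !all(attr_cols %in% names(kinds))) {
      stop("kinds must be a named vector covering every attribute column", call. = FALSE)
    }
    bad <- setdiff(names(kinds), attr_cols)
    if (length(bad)) {
      stop("kinds declared for unknown column(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    kinds <- kinds[attr_cols]
    ok <- kinds %in% c("binary", "discrete", "continuous")
    if (!all(ok)) stop("unknown variable kind: ", paste(unique(kinds[!ok]), collapse = ", "), call. = FALSE)
  }
  raw_missing <- mean(is.na(as.matrix(data[attr_cols])))
  new_dataset(data, class, kinds, domain, name, raw_missing)
}

new_dataset <- function(data, class_col, kinds, domain, name, raw_missing_ratio,
                        provenance = list(dropped_columns = character(), dropped_rows = integer())) {
  structure(
    tibble::as_tibble(data),
    class_col = class_col,
    kinds = kinds,
    domain = domain,
    ds_name = name,
    raw_missing_ratio = raw_missing_ratio,
    provenance = provenance,
    class = c("algsel_dataset", class(tibble::tibble()))
  )
}

# rebuild the dataset wrapper after a base-subsetting operation
restore_dataset <- function(data, template, kinds = NULL, provenance = NULL) {
  new_dataset(
    data,
    class_col = dataset_class(template),
    kinds = if (is.null(kinds)) dataset_kinds(template)[setdiff(names(data), dataset_class(template))] else kinds,
    domain = dataset_domain(template),
    name = dataset_name(template),
    raw_missing_ratio = attr(template, "raw_missing_ratio"),
    provenance = if (is.null(provenance)) attr(template, "provenance") else provenance
  )
}

#' @rdname as_dataset
#' @param x An `algsel_dataset`.
#' @export
dataset_class <- function(x) attr(x, "class_col")

#' @rdname as_dataset
#' @export
dataset_kinds <- function(x) attr(x, "kinds")

#' @rdname as_dataset
#' @export
dataset_domain <- function(x) attr(x, "domain")

#' @rdname as_dataset
#' @export
dataset_name <- function(x) attr(x, "ds_name")

#' @rdname as_dataset
#' @export
attribute_names <- function(x) setdiff(names(x), dataset_class(x))

#' @export
print.algsel_dataset <- function(x, ...) {
  cat(sprintf(
    "<algsel_dataset '%s'> %d x %d attributes, class '%s' (%d levels), domain %s, raw missing %.1f%%\n",
    dataset_name(x), nrow(x), length(attribute_names(x)), dataset_class(x),
    length(unique(x[[dataset_class(x)]])), dataset_domain(x),
    100 * attr(x, "raw_missing_ratio")
  ))
  NextMethod()
}

#' Infer variable kinds from column contents
#'
#' Fallback used when a schema does not declare kinds: a column with exactly
#' two distinct observed values is binary; a non-numeric column, or a numeric
#' one with at most `max_discrete_cardinality` distinct values, is discrete;
#' anything else is continuous. Constant columns are degenerate but kept, as
#' discrete.
#'
#' @param data Data frame of attribute columns (no class column).
#' @param max_discrete_cardinality Largest number of distinct numeric values
#'   still read as a discrete code rather than a measurement.
#' @return Named character vector of kinds.
#' @export
infer_variable_kinds <- function(data, max_discrete_cardinality = 10L) {
  stopifnot(is.data.frame(data), max_discrete_cardinality >= 1L)
  vapply(data, function(col) {
    vals <- unique(col[!is.na(col)])
    k <- length(vals)
    if (k == 2L) return("binary")
    if (!is.numeric(col) || k <= max_discrete_cardinality) return("discrete")
    "continuous"
  }, character(1))
}

#' Read a delimited dataset with a schema sidecar
#'
#' Reads an RFC-4180-style delimited file and wraps it as an
#' [as_dataset()] object according to a schema that names every column, marks
#' the class column and tags the domain. The schema is either a YAML file
#' path or an equivalent list with elements `columns` (list of
#' `{name, kind}`; `kind` may be omitted to infer), `class`, `domain`, and
#' optionally `delimiter` and `na` (missing-value sentinels, default empty
#' string, `"?"` and `"NA"`).
#'
#' @param path Path to the delimited text file.
#' @param schema Path to a YAML schema file, or a list.
#' @param name Dataset name; defaults to the file stem.
#' @return An `algsel_dataset`.
#' @export
read_dataset <- function(path, schema, name = NULL) {
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  stopifnot(is.list(schema), !is.null(schema$columns), !is.null(schema$class))
  delim <- schema$delimiter %||% ","
  na <- schema$na %||% c("", "?", "NA")
  raw <- readr::read_delim(path, delim = delim, na = na, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  declared <- vapply(schema$columns, function(c) c$name, character(1))
  missing_cols <- setdiff(names(raw), declared)
  if (length(missing_cols)) {
    stop("schema does not name column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(declared, names(raw))
  if (length(unknown)) {
    stop("schema names unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  kinds <- vapply(schema$columns, function(c) c$kind %||% NA_character_, character(1))
  names(kinds) <- declared
  kinds <- kinds[setdiff(declared, schema$class)]
  if (anyNA(kinds)) {
    inferred <- infer_variable_kinds(raw[names(kinds)[is.na(kinds)]])
    kinds[names(inferred)] <- inferred
  }
  as_dataset(raw, class = schema$class, kinds = kinds,
             domain = schema$domain %||% "general",
             name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Read an ARFF dataset
#'
#' Nominal attributes map to discrete kinds (two levels to binary), numeric
#' attributes to continuous.
#'
#' @param path Path to an ARFF file.
#' @param class Class column name; defaults to the last column.
#' @param domain Domain tag.
#' @param name Dataset name; defaults to the file stem.
#' @return An `algsel_dataset`.
#' @export
read_arff_dataset <- function(path, class = NULL, domain = "general", name = NULL) {
  raw <- foreign::read.arff(path)
  class <- class %||% names(raw)[ncol(raw)]
  attr_cols <- setdiff(names(raw), class)
  kinds <- vapply(raw[attr_cols], function(col) {
    if (is.numeric(col)) return("continuous")
    if (nlevels(factor(col)) == 2L) "binary" else "discrete"
  }, character(1))
  as_dataset(raw, class = class, kinds = kinds, domain = domain,
             name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Remove attributes with too many missing values
#'
#' Drops every attribute whose missing fraction strictly exceeds `threshold`
#' (default 30%), the guard that prevents a single badly-collected variable
#' from wiping out most rows under complete-case filtering. Column order is
#' otherwise preserved, and the decision for each column depends only on that
#' column's own missing fraction.
#'
#' @param data An `algsel_dataset`.
#' @param threshold Missing fraction above which an attribute is removed;
#'   strictly-greater comparison, so exactly 30% missing is retained.
#' @return The dataset without the sparse attributes; dropped names are
#'   appended to the provenance log.
#' @export
drop_sparse_attributes <- function(data, threshold = 0.30) {
  stopifnot(inherits(data, "algsel_dataset"), threshold > 0, threshold < 1)
  cls <- dataset_class(data)
  attrs <- attribute_names(data)
  frac <- vapply(data[attrs], function(col) mean(is.na(col)), numeric(1))
  drop <- attrs[frac > threshold]
  keep <- setdiff(names(data), drop)
  if (!any(setdiff(keep, cls) %in% attrs) || length(keep) <= 1L) {
    stop("degenerate dataset: every attribute exceeds the missingness threshold", call. = FALSE)
  }
  prov <- attr(data, "provenance")
  prov$dropped_columns <- c(prov$dropped_columns, drop)
  restore_dataset(data[keep], data, provenance = prov)
}

#' Remove rows containing missing values
#'
#' Complete-case filter applied after [drop_sparse_attributes()]; imputation
#' is deliberately not offered, since filled-in values would distort the
#' characteristic indicators the pipeline exists to measure.
#'
#' @param data An `algsel_dataset`.
#' @return The dataset restricted to complete rows, class labels kept
#'   aligned; dropped row indices go to the provenance log.
#' @export
drop_incomplete_rows <- function(data) {
  stopifnot(inherits(data, "algsel_dataset"))
  complete <- stats::complete.cases(data[attribute_names(data)])
  if (!any(complete)) {
    stop("degenerate dataset: no complete rows remain", call. = FALSE)
  }
  prov <- attr(data, "provenance")
  prov$dropped_rows <- c(prov$dropped_rows, which(!complete))
  restore_dataset(data[complete, , drop = FALSE], data, provenance = prov)
}

#' Preprocess a dataset for characterization and benchmarking
#'
#' Applies the two missing-data rules in their stated order — sparse
#' attributes first, then incomplete rows — so that an attribute with heavy
#' missingness is removed before it can trigger mass row deletion. The raw
#' missing ratio recorded at load time is retained, and a provenance log of
#' dropped columns and row indices is attached. The operation is idempotent.
#'
#' @param data An `algsel_dataset`.
#' @param threshold Attribute missingness cutoff passed to
#'   [drop_sparse_attributes()].
#' @return A complete-case `algsel_dataset`.
#' @export
preprocess <- function(data, threshold = 0.30) {
  drop_incomplete_rows(drop_sparse_attributes(data, threshold))
}

#' Dataset category by attribute kinds
#'
#' `"continuous"` when every attribute is continuous, `"discrete"` when every
#' attribute is discrete or binary, `"mixed"` otherwise. The category selects
#' which block of the published formula bank applies.
#'
#' @param data An `algsel_dataset`.
#' @return One of `"mixed"`, `"discrete"`, `"continuous"`.
#' @export
dataset_category <- function(data) {
  kinds <- dataset_kinds(data)
  stopifnot(length(kinds) >= 1L)
  if (all(kinds == "continuous")) return("continuous")
  if (all(kinds %in% c("binary", "discrete"))) return("discrete")
  "mixed"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
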