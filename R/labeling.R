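#' Rank algorithms on one dataset
#'
#' Completed records are ordered by test accuracy (descending); ties are
#' broken by the least-class recall (descending), then log10 modeling time
#' (ascending), then the fixed algorithm order of [algorithm_ids()]. Failed
#' records occupy the trailing ranks. Ranking is invariant to the input row
#' order.
#'
#' @param records Benchmark records for a single dataset (one row per
#'   algorithm).
#' @return The records with a `rank` column, ordered by rank.
#' @export
rank_algorithms <- function(records) {
  if (length(unique(records$dataset_name)) != 1L) {
    stop("records must all belong to one dataset", call. = FALSE)
  }
  if (!any(records$status == "completed")) {
    stop("degenerate ranking: no algorithm completed on '",
         records$dataset_name[1], "'", call. = FALSE)
  }
  ord <- records |>
    dplyr::mutate(.fixed = match(.data$algorithm, algorithm_ids()),
                  .failed = .data$status != "completed") |>
    dplyr::arrange(.data$.failed, dplyr::desc(.data$acc_test),
                   dplyr::desc(.data$s_least), .data$log10_time, .data$.fixed) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(-".fixed", -".failed")
  ord
}

#' Discretize a ranking into recommendation labels
#'
#' Ranks 1-3 become recommended (`Y`), ranks 4-5 medium (`M`), ranks 6-8 and
#' every modeling failure not recommended (`No`). When fewer than three
#' algorithms complete, all completed ones are `Y` (the top-3 rule applied to
#' the ranks that exist).
#'
#' @param ranking Output of [rank_algorithms()].
#' @return Tibble with columns `dataset_name`, `algorithm`, `label` and a
#'   binary `recommended` column (`Y` vs not).
#' @export
assign_labels <- function(ranking) {
  ranking |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$status != "completed" ~ "No",
        .data$rank <= 3L ~ "Y",
        .data$rank <= 5L ~ "M",
        TRUE ~ "No"
      ),
      recommended = .data$label == "Y"
    ) |>
    dplyr::select("dataset_name", "algorithm", "rank", "status", "label", "recommended")
}

#' Label every dataset in a benchmark table
#'
#' @param records An `algsel_benchmark` tibble covering one or more datasets.
#' @return Tibble of per-(dataset, algorithm) labels.
#' @export
label_benchmark <- function(records) {
  records |>
    dplyr::group_split(.data$dataset_name) |>
    purrr::map_dfr(function(g) assign_labels(rank_algorithms(g)))
}
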