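#' Rank markers by literature hit counts
#'
#' Descending hit count; ties broken by marker-name lexicographic order so
#' the ranking is deterministic.
#'
#' @param table data.frame with columns `marker` (unique names) and
#'   `hit_count` (non-negative integers).
#' @param k number of top markers to return.
#' @return character vector of the top-k marker names, in rank order.
#' @export
rank_by_hits <- function(table, k) {
  stopifnot(all(c("marker", "hit_count") %in% names(table)))
  if (anyDuplicated(table$marker))
    stop("duplicate marker names in the literature table", call. = FALSE)
  if (any(table$hit_count < 0)) stop("negative hit counts", call. = FALSE)
  if (k > nrow(table))
    stop("k exceeds the number of markers", call. = FALSE)
  ord <- order(-table$hit_count, table$marker, method = "radix")
  table$marker[ord][seq_len(k)]
}

#' Union of the top-k markers of two rankings
#'
#' Combines a literature ranking and a data-driven (forest) ranking by
#' taking the union of their top-k members; overlapping markers are
#' reported with source `"both"`.
#'
#' @param lit_ranks character vector, literature ranking (best first).
#' @param forest_ranks character vector, forest minimal-depth ranking.
#' @param k how many from each list (default 10).
#' @return data.frame with columns `marker` and `source`
#'   (`literature` / `forest` / `both`), literature-first ordering.
#' @export
select_top_union <- function(lit_ranks, forest_ranks, k = 10L) {
  if (k > length(lit_ranks) || k > length(forest_ranks))
    stop("k exceeds a ranking length", call. = FALSE)
  top_lit <- lit_ranks[seq_len(k)]
  top_for <- forest_ranks[seq_len(k)]
  markers <- unique(c(top_lit, top_for))
  source <- ifelse(markers %in% top_lit & markers %in% top_for, "both",
                   ifelse(markers %in% top_lit, "literature", "forest"))
  data.frame(marker = markers, source = source, stringsAsFactors = FALSE)
}
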