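#' Define a forum subtype
#'
#' A subtype is a labelled group of forums; its commenter set is the exact
#' union of the member forums' commenter sets.
#'
#' @param label Free-text subtype label.
#' @param forums Non-empty character vector of member forum names.
#' @param commenter_index Named list, forum -> commenter set, covering all
#'   members.
#' @return A list with `label`, `forums`, `commenters`.
#' @export
subtype_definition <- function(label, forums, commenter_index) {
  stopifnot(length(forums) > 0)
  missing <- setdiff(forums, names(commenter_index))
  if (length(missing) > 0) {
    stop("unknown forum(s) in subtype definition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  commenters <- sort(unique(unlist(commenter_index[forums],
                                   use.names = FALSE)))
  list(label = label, forums = forums, commenters = commenters)
}

#' Minimum commenter count for ancillary inclusion
#'
#' The smallest integer count `n` such that `n / n_subtype_commenters`
#' reaches 1% — i.e. the ceiling of 1% of the subtype's commenters. An
#' ancillary forum reached by fewer subtype commenters is excluded.
#'
#' @param n_subtype_commenters Size of the subtype's commenter set.
#' @param inclusion_proportion Inclusion fraction (default 0.01).
#' @return Integer minimum count.
#' @export
#' @examples
#' ancillary_inclusion_threshold(8166) # 82
#' ancillary_inclusion_threshold(1580) # 16
ancillary_inclusion_threshold <- function(n_subtype_commenters,
                                          inclusion_proportion = 0.01) {
  stopifnot(n_subtype_commenters >= 1, inclusion_proportion > 0)
  as.integer(ceiling(inclusion_proportion * n_subtype_commenters))
}

#' Find a subtype's ancillary forum candidates
#'
#' Every forum outside the subtype's member list that at least the
#' inclusion threshold of subtype commenters contributed to. Forums that
#' belong to other subtypes are eligible.
#'
#' @param commenter_index_all Named list covering all forums in the
#'   archive.
#' @param subtype A [subtype_definition()].
#' @param inclusion_proportion Inclusion fraction (default 0.01).
#' @return A tibble (`forum`, `n_subtype_commenters`,
#'   `forum_total_commenters`, `proportion`), where `proportion` is the
#'   share of the forum's own commenters that belong to the subtype.
#' @export
find_ancillary_forums <- function(commenter_index_all, subtype,
                                  inclusion_proportion = 0.01) {
  threshold <- ancillary_inclusion_threshold(length(subtype$commenters),
                                             inclusion_proportion)
  others <- setdiff(names(commenter_index_all), subtype$forums)
  counts <- vapply(commenter_index_all[others], function(s) {
    length(intersect(unique(s), subtype$commenters))
  }, integer(1))
  totals <- vapply(commenter_index_all[others],
                   function(s) length(unique(s)), integer(1))
  keep <- counts >= threshold
  tibble::tibble(
    forum = others[keep],
    n_subtype_commenters = unname(counts[keep]),
    forum_total_commenters = unname(totals[keep]),
    proportion = unname(counts[keep] / totals[keep])
  )
}

#' Dual-rank ancillary forums
#'
#' Ranks candidates separately in descending order of (1) the number of
#' subtype commenters contributing to the forum and (2) the proportion of
#' the forum's total commenters who belong to the subtype, then averages
#' the two ranks. Rank 1 is the largest value; ties receive the average of
#' the tied positions (fractional ranking). The result is sorted by mean
#' rank, best first, ties broken by forum name.
#'
#' @param candidates Tibble from [find_ancillary_forums()].
#' @return The candidates tibble with `rank_by_count`,
#'   `rank_by_proportion` and `mean_rank` columns added, sorted ascending
#'   by `mean_rank`.
#' @export
rank_ancillary_forums <- function(candidates) {
  stopifnot(nrow(candidates) > 0,
            all(c("forum", "n_subtype_commenters", "proportion")
                %in% names(candidates)))
  out <- candidates
  out$rank_by_count <- rank(-out$n_subtype_commenters,
                            ties.method = "average")
  out$rank_by_proportion <- rank(-out$proportion, ties.method = "average")
  out$mean_rank <- (out$rank_by_count + out$rank_by_proportion) / 2
  out[order(out$mean_rank, out$forum), ]
}

#' Select the top-ranked ancillary forums
#'
#' The `k` forums with the best (numerically smallest) mean rank: forums
#' both large in subtype-commenter count and with a high subtype share.
#' When fewer than `k` candidates exist, all are returned with a warning.
#'
#' @param ranking Tibble from [rank_ancillary_forums()].
#' @param k Number of forums to select (default 50).
#' @return Character vector of forum names in rank order.
#' @export
select_top_k <- function(ranking, k = 50) {
  stopifnot(k >= 1)
  if (nrow(ranking) < k) {
    warning(sprintf("only %d candidate(s) available for top-%d selection",
                    nrow(ranking), k), call. = FALSE)
    k <- nrow(ranking)
  }
  ranking$forum[seq_len(k)]
}

#' Overlap matrix restricted to a subtype's commenters
#'
#' Identical to [build_overlap_matrix()] except that each forum's
#' commenter set is first intersected with the subtype's commenter set:
#' overlap among ancillary forums is measured only through the subtype's
#' own commenters.
#'
#' @param commenter_index_all Named list covering the forums.
#' @param forums Forums to include (typically from [select_top_k()]).
#' @param subtype_commenters The subtype's commenter set.
#' @return A symmetric overlap matrix as in [build_overlap_matrix()].
#' @export
restricted_overlap_matrix <- function(commenter_index_all, forums,
                                      subtype_commenters) {
  stopifnot(length(subtype_commenters) > 0)
  missing <- setdiff(forums, names(commenter_index_all))
  if (length(missing) > 0) {
    stop("forum(s) missing from commenter index: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  restricted <- lapply(commenter_index_all[forums], intersect,
                       y = subtype_commenters)
  empty <- names(restricted)[lengths(restricted) == 0]
  if (length(empty) > 0) {
    stop("forum(s) share no commenters with the subtype: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  build_overlap_matrix(restricted, forums)
}
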