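#' Exhaustive Venn region counts across community commenter sets
#'
#' Classifies every commenter in the union of the community sets by the
#' exact subset of communities they posted in, giving the count of each of
#' the `2^k - 1` non-empty regions of the k-set Venn diagram. The region
#' table is the normative output; any diagram drawn from it is unscaled
#' decoration.
#'
#' @param community_sets Named list, community label -> commenter set.
#' @return A tibble (`region`, `communities`, `n_communities`, `count`):
#'   one row per region, `region` a label like `"A&B"` joining member
#'   community labels with `&` in input order, `communities` the
#'   list-column of labels. Counts are disjoint and sum to the size of the
#'   union. Attribute `universe_size` carries the union size.
#' @export
venn_partition <- function(community_sets) {
  k <- length(community_sets)
  stopifnot(k >= 1, !is.null(names(community_sets)))
  labels <- names(community_sets)
  sets <- lapply(community_sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  # membership pattern per commenter, encoded as a k-bit signature
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  signature <- apply(member, 1, function(row) paste(as.integer(row),
                                                    collapse = ""))
  # all 2^k - 1 non-empty subsets, ordered by size then position
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  region_sig <- apply(subsets, 1, function(row) paste(as.integer(row),
                                                      collapse = ""))
  counts <- table(signature)
  out <- tibble::tibble(
    region = apply(subsets, 1, function(row) paste(labels[unlist(row)],
                                                   collapse = "&")),
    communities = apply(subsets, 1, function(row) list(labels[unlist(row)])),
    n_communities = rowSums(subsets),
    count = as.integer(ifelse(region_sig %in% names(counts),
                              counts[region_sig], 0L))
  )
  out <- out[order(out$n_communities, out$region), ]
  out$communities <- lapply(out$communities, unlist)
  attr(out, "universe_size") <- length(universe)
  out
}

#' Exclusive and shared commenter counts between two community groups
#'
#' Partitions the universe of commenters into those who posted only in
#' communities of the first group, only in the second, or in both, with
#' each count also expressed as a percentage of the universe (2 decimals,
#' half-up). The two groups must not share a community.
#'
#' @param community_sets Named list, community label -> commenter set.
#' @param group_a,group_b Disjoint character vectors of community labels.
#' @param group_names Length-2 labels for reporting (defaults "a", "b").
#' @return A list with `counts` (`only_a`, `only_b`, `both`, `neither`),
#'   `percentages` (of the universe, for only_a/only_b/both),
#'   `universe_size` and `group_names`.
#' @export
group_exclusive_counts <- function(community_sets, group_a, group_b,
                                   group_names = c("a", "b")) {
  stopifnot(all(group_a %in% names(community_sets)),
            all(group_b %in% names(community_sets)))
  if (length(intersect(group_a, group_b)) > 0) {
    stop("group definitions overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "), call. = FALSE)
  }
  universe <- unique(unlist(community_sets, use.names = FALSE))
  in_a <- universe %in% unique(unlist(community_sets[group_a],
                                      use.names = FALSE))
  in_b <- universe %in% unique(unlist(community_sets[group_b],
                                      use.names = FALSE))
  counts <- c(only_a = sum(in_a & !in_b), only_b = sum(!in_a & in_b),
              both = sum(in_a & in_b), neither = sum(!in_a & !in_b))
  list(
    counts = counts,
    percentages = c(only_a = pct(counts[["only_a"]], length(universe)),
                    only_b = pct(counts[["only_b"]], length(universe)),
                    both = pct(counts[["both"]], length(universe))),
    universe_size = length(universe),
    group_names = group_names
  )
}

#' Per-community participation percentages
#'
#' For each community, the percentage of the universe's commenters who
#' posted in it (2 decimals, half-up). Membership is non-exclusive, so
#' the percentages may sum to more than 100.
#'
#' @param community_sets Named list, community label -> commenter set.
#' @param universe Character vector of commenters forming the denominator.
#' @return A tibble (`community`, `n_commenters`, `percentage`).
#' @export
community_participation <- function(community_sets, universe) {
  stopifnot(length(universe) > 0)
  universe <- unique(universe)
  n <- vapply(community_sets, function(s) {
    length(intersect(unique(s), universe))
  }, integer(1))
  tibble::tibble(
    community = names(community_sets),
    n_commenters = unname(n),
    percentage = pct(unname(n), length(universe))
  )
}

#' Coverage of a subtype by the selected ancillary forums
#'
#' Percentage of the subtype's commenters who posted on at least one of
#' the selected forums (2 decimals, half-up).
#'
#' @param subtype_commenters Non-empty commenter set.
#' @param selected_forum_sets List of the selected forums' commenter sets.
#' @return A list with `n_covered`, `n_subtype`, `percentage`.
#' @export
coverage <- function(subtype_commenters, selected_forum_sets) {
  stopifnot(length(subtype_commenters) > 0)
  subtype_commenters <- unique(subtype_commenters)
  pool <- unique(unlist(selected_forum_sets, use.names = FALSE))
  n_cov <- length(intersect(subtype_commenters, pool))
  list(n_covered = n_cov, n_subtype = length(subtype_commenters),
       percentage = pct(n_cov, length(subtype_commenters)))
}

#' Bot-named account report
#'
#' Flags accounts whose name contains "bot" (case-insensitive substring)
#' and summarizes their activity. Flagging is reporting-only — bots are
#' deliberately never filtered out, a conservative choice given that bot
#' heuristics also catch real users.
#'
#' @param commenter_activity_counts Named numeric vector, commenter name
#'   -> comment count.
#' @return A list with `n_flagged`, `n_total`, `fraction_percentage`
#'   (2 decimals, half-up) and `stats` (mean, sd, median, min, max of the
#'   flagged accounts' comment counts; all `NA` when none are flagged).
#' @export
bot_name_report <- function(commenter_activity_counts) {
  nm <- names(commenter_activity_counts)
  stopifnot(!is.null(nm))
  flagged <- grepl("bot", nm, ignore.case = TRUE)
  x <- commenter_activity_counts[flagged]
  stats <- if (length(x) == 0) {
    c(mean = NA_real_, sd = NA_real_, median = NA_real_,
      min = NA_real_, max = NA_real_)
  } else {
    c(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
      min = min(x), max = max(x))
  }
  list(
    n_flagged = sum(flagged),
    n_total = length(commenter_activity_counts),
    fraction_percentage = if (length(commenter_activity_counts) > 0) {
      pct(sum(flagged), length(commenter_activity_counts))
    } else NA_real_,
    flagged_names = nm[flagged],
    stats = stats
  )
}
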