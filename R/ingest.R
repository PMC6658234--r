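#' Field mapping for a comment archive
#'
#' Maps the column names found in a JSON-lines comment archive onto the
#' canonical record fields used throughout the package. The defaults match
#' the schema of the public Reddit (Pushshift-style) monthly comment dumps.
#'
#' @param author,forum,thread_id,created_utc,body Source field names.
#' @return A named character vector (canonical field -> source field).
#' @export
#' @examples
#' archive_schema() # Pushshift defaults
#' archive_schema(forum = "board", thread_id = "topic")
archive_schema <- function(author = "author", forum = "subreddit",
                           thread_id = "link_id", created_utc = "created_utc",
                           body = "body") {
  c(author = author, forum = forum, thread_id = thread_id,
    created_utc = created_utc, body = body)
}

#' Accounts excluded from all analyses
#'
#' The platform's generic moderation bot and the placeholder left when an
#' account is deleted. Comparison is exact (account names are
#' case-sensitive identities).
#'
#' @return Character vector of account names.
#' @export
default_excluded_authors <- function() {
  c("AutoModerator", "[deleted]")
}

#' Read a JSON-lines comment archive
#'
#' Parses one comment per line into a record table. Malformed lines and
#' lines missing a mapped field are counted and skipped with a warning
#' rather than aborting: multi-gigabyte public dumps routinely contain a
#' few damaged lines.
#'
#' @param path Path to the archive (plain or gzip-compressed JSON lines).
#' @param schema Field mapping from [archive_schema()].
#' @return A tibble with columns `author`, `forum`, `thread_id`,
#'   `created_utc` (seconds since epoch, UTC) and `body`, with attribute
#'   `n_skipped` giving the number of lines dropped.
#' @export
read_comment_archive <- function(path, schema = archive_schema()) {
  if (!file.exists(path)) {
    stop("archive file does not exist: ", path, call. = FALSE)
  }
  stopifnot(all(c("author", "forum", "thread_id", "created_utc", "body")
                %in% names(schema)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble::tibble(author = character(), forum = character(),
                          thread_id = character(), created_utc = double(),
                          body = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  valid <- vapply(lines, jsonlite::validate, logical(1), USE.NAMES = FALSE)
  n_skipped <- sum(!valid)
  df <- jsonlite::stream_in(textConnection(lines[valid]), verbose = FALSE)

  take <- function(src) {
    if (src %in% names(df)) df[[src]] else rep(NA, nrow(df))
  }
  out <- tibble::tibble(
    author = as.character(take(schema[["author"]])),
    forum = as.character(take(schema[["forum"]])),
    thread_id = as.character(take(schema[["thread_id"]])),
    created_utc = suppressWarnings(as.numeric(take(schema[["created_utc"]]))),
    body = as.character(take(schema[["body"]]))
  )
  complete <- !is.na(out$author) & !is.na(out$forum) &
    !is.na(out$thread_id) & !is.na(out$created_utc) & !is.na(out$body) &
    nzchar(out$author) & nzchar(out$forum) & nzchar(out$thread_id)
  n_skipped <- n_skipped + sum(!complete)
  out <- out[complete, ]
  if (n_skipped > 0) {
    warning(sprintf("skipped %d malformed or incomplete archive line(s)",
                    n_skipped), call. = FALSE)
  }
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

month_bounds <- function(window_start, window_end) {
  parse_month <- function(x, what) {
    if (!grepl("^\\d{4}-\\d{2}$", x)) {
      stop(what, " must be a 'YYYY-MM' string, got: ", x, call. = FALSE)
    }
    as.POSIXct(paste0(x, "-01 00:00:00"), tz = "UTC")
  }
  start <- parse_month(window_start, "window_start")
  end_first <- parse_month(window_end, "window_end")
  if (end_first < start) {
    stop("window_end precedes window_start", call. = FALSE)
  }
  # last second of the end month: first second of the next month, minus 1
  end <- seq(end_first, by = "1 month", length.out = 2)[2] - 1
  c(start = as.numeric(start), end = as.numeric(end))
}

#' Apply the corpus inclusion window and account exclusions
#'
#' Retains records whose timestamp falls within the calendar-month window
#' (both ends inclusive, UTC) and whose author is not on the exclusion
#' list. Author comparison is exact and case-sensitive.
#'
#' @param records Record tibble from [read_comment_archive()].
#' @param window_start,window_end First and last month of the window as
#'   `"YYYY-MM"` strings, e.g. `"2017-03"` and `"2018-02"`.
#' @param excluded_authors Account names to drop entirely
#'   (default [default_excluded_authors()]).
#' @return The filtered record tibble.
#' @export
filter_records <- function(records, window_start, window_end,
                           excluded_authors = default_excluded_authors()) {
  bounds <- month_bounds(window_start, window_end)
  keep <- records$created_utc >= bounds[["start"]] &
    records$created_utc <= bounds[["end"]] &
    !(records$author %in% excluded_authors)
  out <- records[keep, ]
  attr(out, "n_skipped") <- attr(records, "n_skipped")
  out
}

#' Find candidate forums by search term
#'
#' Selects forums whose name or brief description contains any search term
#' (case-insensitive substring match), then removes private forums and any
#' manually excluded names (forums that match a term but are unrelated to
#' the topic of interest).
#'
#' @param forum_meta Data frame with columns `name`, `description`,
#'   `is_private`.
#' @param search_terms Non-empty character vector of terms.
#' @param manual_exclusions Forum names to drop, matched case-insensitively.
#' @return Sorted character vector of forum names (possibly empty).
#' @export
discover_forums <- function(forum_meta, search_terms,
                            manual_exclusions = character()) {
  stopifnot(all(c("name", "description", "is_private") %in% names(forum_meta)),
            length(search_terms) > 0)
  folded <- tolower(forum_meta$name)
  if (anyDuplicated(folded)) {
    stop("forum names are not unique under case-folding", call. = FALSE)
  }
  haystack <- tolower(paste(forum_meta$name, forum_meta$description))
  hit <- rep(FALSE, nrow(forum_meta))
  for (term in tolower(search_terms)) {
    hit <- hit | grepl(term, haystack, fixed = TRUE)
  }
  keep <- hit & !forum_meta$is_private &
    !(folded %in% tolower(manual_exclusions))
  sort(forum_meta$name[keep])
}

#' Build the commenter and thread indices
#'
#' From filtered records, compiles for each forum the set of distinct
#' commenters and the comment bodies of each thread. These two indices are
#' the inputs to every downstream network and text-mining stage.
#'
#' @param records Filtered record tibble.
#' @param forum_whitelist Optional character vector; if given, only these
#'   forums are indexed.
#' @return A list with elements:
#'   * `commenters`: named list, forum -> character vector of distinct
#'     commenter names;
#'   * `threads`: tibble (`forum`, `thread_id`, `body`), one row per
#'     comment.
#' @export
build_indices <- function(records, forum_whitelist = NULL) {
  if (!is.null(forum_whitelist)) {
    records <- records[records$forum %in% forum_whitelist, ]
  }
  commenters <- lapply(
    split(records$author, factor(records$forum)),
    function(x) sort(unique(x))
  )
  threads <- tibble::tibble(
    forum = records$forum,
    thread_id = records$thread_id,
    body = records$body
  )
  list(commenters = commenters[order(names(commenters))], threads = threads)
}

#' Drop forums below the minimum-commenter threshold
#'
#' Restricts the analysis to forums with at least `min_commenters` distinct
#' included commenters in the window; a forum with exactly the threshold is
#' retained ("fewer than" is strict).
#'
#' @param commenter_index Named list, forum -> commenter set (the
#'   `commenters` element of [build_indices()]).
#' @param min_commenters Minimum distinct commenters (default 500).
#' @return Sorted character vector of retained forum names.
#' @export
apply_min_commenter_threshold <- function(commenter_index,
                                          min_commenters = 500) {
  stopifnot(min_commenters >= 1)
  sizes <- lengths(commenter_index)
  sort(names(commenter_index)[sizes >= min_commenters])
}

#' Read a forum metadata table
#'
#' @param path CSV file with columns `name`, `description`, `is_private`.
#' @return A tibble with `is_private` coerced to logical.
#' @export
read_forum_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "description", "is_private") %in% names(df)))
  df$is_private <- as.logical(df$is_private)
  tibble::as_tibble(df)
}

#' Write the commenter and thread indices as CSV
#'
#' Emits two plain CSV files: `(forum, commenter)` pairs and per-thread
#' comment counts `(forum, thread_id, n_comments)`.
#'
#' @param indices Result of [build_indices()].
#' @param commenters_path,threads_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_indices <- function(indices, commenters_path, threads_path) {
  pairs <- data.frame(
    forum = rep(names(indices$commenters), lengths(indices$commenters)),
    commenter = unlist(indices$commenters, use.names = FALSE)
  )
  utils::write.csv(pairs, commenters_path, row.names = FALSE)
  counts <- stats::aggregate(
    body ~ forum + thread_id, data = indices$threads, FUN = length
  )
  names(counts)[names(counts) == "body"] <- "n_comments"
  counts <- counts[order(counts$forum, counts$thread_id), ]
  utils::write.csv(counts, threads_path, row.names = FALSE)
  invisible(c(commenters_path, threads_path))
}
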