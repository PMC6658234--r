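#' Default recovery term list
#'
#' The five inflections of "recover" counted by the recovery-focus
#' statistic.
#'
#' @return Character vector of terms.
#' @export
recovery_terms <- function() {
  c("recovery", "recover", "recovers", "recovered", "recovering")
}

#' Recovery focus of each forum
#'
#' For each forum, the percentage of its comment threads in which at least
#' one comment contains at least one recovery term. Matching is
#' case-insensitive and whole-word (tokens delimited by non-alphanumeric
#' characters), so "Recovery!" counts but "irrecoverable" does not: the
#' term list enumerates inflections explicitly, which a substring match
#' would collapse. A higher percentage is read as a greater recovery
#' focus.
#'
#' @param thread_index Tibble (`forum`, `thread_id`, `body`), one row per
#'   comment (the `threads` element of [build_indices()]).
#' @param terms Term list (default [recovery_terms()]).
#' @param forums Optional subset of forums to report (default: all in the
#'   index). A requested forum with zero threads is an error: its
#'   percentage is undefined.
#' @return A tibble with columns `forum`, `threads_total`,
#'   `threads_with_term`, `percentage` (2 decimal places, half-up).
#' @export
recovery_focus <- function(thread_index, terms = recovery_terms(),
                           forums = NULL) {
  stopifnot(length(terms) > 0,
            all(c("forum", "thread_id", "body") %in% names(thread_index)))
  if (is.null(forums)) {
    forums <- sort(unique(thread_index$forum))
  } else {
    absent <- setdiff(forums, thread_index$forum)
    if (length(absent) > 0) {
      stop("forum(s) with zero threads: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(forums) == 0) {
    stop("no forums with threads to report", call. = FALSE)
  }
  pattern <- paste0("(?<![[:alnum:]])(",
                    paste(vapply(terms, escape_regex, character(1)),
                          collapse = "|"),
                    ")(?![[:alnum:]])")
  idx <- thread_index[thread_index$forum %in% forums, ]
  hit <- grepl(pattern, idx$body, ignore.case = TRUE, perl = TRUE)
  key <- paste(idx$forum, idx$thread_id, sep = "\r")
  thread_hit <- tapply(hit, key, any)
  thread_forum <- sub("\r.*$", "", names(thread_hit))
  totals <- table(factor(thread_forum, levels = forums))
  with_term <- tapply(as.vector(thread_hit),
                      factor(thread_forum, levels = forums),
                      sum, default = 0)
  tibble::tibble(
    forum = forums,
    threads_total = as.integer(totals[forums]),
    threads_with_term = as.integer(with_term[forums]),
    percentage = pct(as.integer(with_term[forums]),
                     as.integer(totals[forums]))
  )
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Recovery-focus difference between two forums
#'
#' Signed difference in percentage points between two recovery-focus
#' report rows; positive means the first forum is more recovery-focused.
#'
#' @param report_a,report_b Single rows of a [recovery_focus()] report (or
#'   any list with a `percentage` field).
#' @return Difference `percentage_a - percentage_b` in percentage points.
#' @export
recovery_focus_difference <- function(report_a, report_b) {
  stopifnot(!is.null(report_a$percentage), !is.null(report_b$percentage))
  report_a$percentage - report_b$percentage
}
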