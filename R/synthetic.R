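#' Configuration for the synthetic comment-archive generator
#'
#' Describes a planted-structure comment archive: forums grouped into
#' communities, commenters with a home community and heavy-tailed
#' activity, a small cross-community contribution probability, per-forum
#' recovery-term thread rates, and the platform noise the ingest rules
#' must handle (bot-named accounts, deleted-author placeholders, a
#' moderation bot).
#'
#' @param n_communities Number of planted forum communities.
#' @param forums_per_community Forums in each community.
#' @param n_commenters Number of distinct (non-placeholder) commenters.
#' @param epsilon Probability that a single contribution goes to a forum
#'   outside the commenter's home community.
#' @param activity_alpha Exponent of the discrete power-law activity
#'   distribution `P(k) ~ k^-alpha`, `k = 1..activity_max` (comments per
#'   commenter; heavy-tailed, minimum 1).
#' @param activity_max Upper bound on comments per commenter.
#' @param threads_per_forum Thread count available per forum.
#' @param recovery_rate Probability that a forum thread carries a recovery
#'   term; scalar, or a vector recycled over forums in forum order.
#' @param bot_fraction Fraction of commenters given a bot-style account
#'   name (these behave like ordinary commenters and are never filtered).
#' @param deleted_fraction Extra records attributed to the `[deleted]`
#'   placeholder, as a fraction of ordinary records.
#' @param automod_comments Number of extra `AutoModerator` records.
#' @param window_start,window_end Calendar-month window (`"YYYY-MM"`)
#'   within which timestamps are drawn uniformly.
#' @param seed RNG seed; identical config and seed give a byte-identical
#'   archive.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_communities = 3,
                             forums_per_community = 5,
                             n_commenters = 3000,
                             epsilon = 0.05,
                             activity_alpha = 2,
                             activity_max = 100,
                             threads_per_forum = 40,
                             recovery_rate = 0.1,
                             bot_fraction = 0.007,
                             deleted_fraction = 0.02,
                             automod_comments = 25,
                             window_start = "2017-03",
                             window_end = "2018-02",
                             seed = 1) {
  cfg <- list(n_communities = n_communities,
              forums_per_community = forums_per_community,
              n_commenters = n_commenters, epsilon = epsilon,
              activity_alpha = activity_alpha, activity_max = activity_max,
              threads_per_forum = threads_per_forum,
              recovery_rate = recovery_rate, bot_fraction = bot_fraction,
              deleted_fraction = deleted_fraction,
              automod_comments = automod_comments,
              window_start = window_start, window_end = window_end,
              seed = seed)
  probs <- c(epsilon = epsilon, bot_fraction = bot_fraction,
             deleted_fraction = deleted_fraction)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(recovery_rate < 0) || any(recovery_rate > 1)) {
    stop("recovery_rate must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_communities >= 1, forums_per_community >= 1,
            n_commenters >= 1, activity_alpha > 0, activity_max >= 1,
            threads_per_forum >= 1, automod_comments >= 0)
  month_bounds(window_start, window_end) # validates the window
  class(cfg) <- "generator_config"
  cfg
}

# comment bodies free of recovery terms; "irrecoverable" exercises the
# whole-word matching rule end to end
plain_vocab <- c(
  "i totally agree with this",
  "thanks for sharing your story",
  "this thread is really helpful",
  "the situation felt irrecoverable at the time",
  "not sure what to make of that",
  "same here honestly",
  "that made my day",
  "can you explain a bit more"
)

recovery_vocab <- c(
  "i am finally recovering and it shows",
  "recovery is possible for everyone",
  "she recovered after a long struggle",
  "he recovers a little more every week",
  "trying to recover one day at a time"
)

#' Generate a synthetic comment archive with known ground truth
#'
#' Emits a JSON-lines archive in the public comment-dump schema (fields
#' `author`, `subreddit`, `link_id`, `created_utc`, `body`) together with
#' the planted ground truth every pipeline stage can be validated
#' against. Each contribution goes to a uniformly chosen forum of the
#' commenter's home community with probability `1 - epsilon` and to a
#' forum of another community otherwise. `AutoModerator` and `[deleted]`
#' records are included so the ingest exclusions are exercised.
#'
#' @param config A [generator_config()].
#' @param path Optional path for the JSON-lines archive; when `NULL`
#'   nothing is written and the records are only returned.
#' @return A list:
#'   * `records`: tibble of all emitted records in canonical field names
#'     and emission order;
#'   * `ground_truth`: list with `forum_community` (named integer),
#'     `commenter_sets` (forum -> planted commenter set, placeholders
#'     excluded), `recovery` (tibble `forum`, `threads_total`,
#'     `threads_with_term`), `bot_names`, `home_community`, and
#'     `n_records`;
#'   * `path`: the archive path, or `NULL`.
#' @export
generate_archive <- function(config, path = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  k <- config$n_communities
  fpc <- config$forums_per_community
  n_forums <- k * fpc
  forum_comm <- rep(seq_len(k), each = fpc)
  forums <- sprintf("synth_c%d_f%d", forum_comm,
                    rep(seq_len(fpc), times = k))
  names(forum_comm) <- forums
  rho <- rep_len(config$recovery_rate, n_forums)

  n <- config$n_commenters
  commenters <- sprintf("user%05d", seq_len(n))
  n_bots <- round(config$bot_fraction * n)
  if (n_bots > 0) {
    bot_idx <- sample.int(n, n_bots)
    commenters[bot_idx] <- sprintf("bot_user%05d", bot_idx)
  }
  home <- sample.int(k, n, replace = TRUE)
  names(home) <- commenters

  act_p <- seq_len(config$activity_max)^(-config$activity_alpha)
  activity <- sample.int(config$activity_max, n, replace = TRUE,
                         prob = act_p)

  total <- sum(activity)
  author <- rep(commenters, activity)
  home_of <- rep(home, activity)
  cross <- stats::runif(total) < config$epsilon
  community <- home_of
  if (k > 1 && any(cross)) {
    shift <- sample.int(k - 1, sum(cross), replace = TRUE)
    community[cross] <- (home_of[cross] - 1 + shift) %% k + 1
  }
  forum_idx <- (community - 1) * fpc +
    sample.int(fpc, total, replace = TRUE)
  thread_idx <- sample.int(config$threads_per_forum, total, replace = TRUE)

  # per (forum, thread) flag: does this thread carry a recovery term?
  thread_flag <- matrix(
    stats::runif(n_forums * config$threads_per_forum) <
      rep(rho, times = config$threads_per_forum),
    nrow = n_forums
  )
  is_recovery <- thread_flag[cbind(forum_idx, thread_idx)]
  body <- character(total)
  body[!is_recovery] <- sample(plain_vocab, sum(!is_recovery),
                               replace = TRUE)
  body[is_recovery] <- sample(recovery_vocab, sum(is_recovery),
                              replace = TRUE)

  bounds <- month_bounds(config$window_start, config$window_end)
  ts <- function(m) {
    as.integer(floor(stats::runif(m, bounds[["start"]],
                                  bounds[["end"]] + 1)))
  }
  records <- tibble::tibble(
    author = author,
    forum = forums[forum_idx],
    thread_id = sprintf("t_%s_%03d", forums[forum_idx], thread_idx),
    created_utc = ts(total),
    body = body
  )

  n_deleted <- round(config$deleted_fraction * total)
  extra_n <- n_deleted + config$automod_comments
  if (extra_n > 0) {
    e_forum <- sample.int(n_forums, extra_n, replace = TRUE)
    e_thread <- sample.int(config$threads_per_forum, extra_n,
                           replace = TRUE)
    extra <- tibble::tibble(
      author = c(rep("[deleted]", n_deleted),
                 rep("AutoModerator", config$automod_comments)),
      forum = forums[e_forum],
      thread_id = sprintf("t_%s_%03d", forums[e_forum], e_thread),
      created_utc = ts(extra_n),
      body = sample(plain_vocab, extra_n, replace = TRUE)
    )
    records <- rbind(records, extra)
    # interleave so placeholders are not trivially grouped at the end
    records <- records[sample.int(nrow(records)), ]
  }

  placeholder <- records$author %in% default_excluded_authors()
  commenter_sets <- lapply(
    split(records$author[!placeholder], records$forum[!placeholder]),
    function(x) sort(unique(x))
  )
  # recovery ground truth over threads that received >= 1 comment from an
  # included (non-placeholder) account, matching the post-exclusion
  # thread universe the text-mining stage sees
  seen <- unique(records[!placeholder, c("forum", "thread_id")])
  seen_f <- match(seen$forum, forums)
  seen_t <- as.integer(sub(".*_", "", seen$thread_id))
  recovery <- tibble::tibble(
    forum = forums,
    threads_total = as.integer(table(factor(seen_f, levels = 1:n_forums))),
    threads_with_term = as.integer(tapply(
      thread_flag[cbind(seen_f, seen_t)],
      factor(seen_f, levels = 1:n_forums), sum, default = 0))
  )

  if (!is.null(path)) {
    out <- as.data.frame(records)
    names(out) <- c("author", "subreddit", "link_id", "created_utc", "body")
    con <- file(path, "w")
    jsonlite::stream_out(out, con, verbose = FALSE)
    close(con)
  }

  list(
    records = records,
    ground_truth = list(
      forum_community = forum_comm,
      commenter_sets = commenter_sets,
      recovery = recovery,
      bot_names = sort(commenters[grepl("bot", commenters)]),
      home_community = home,
      n_records = nrow(records)
    ),
    path = path
  )
}
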