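test_that("archive reading streams valid records and skips damaged lines", {
  lines <- c(
    archive_line("alice", "forumA", "t1", 1500000000, "hello"),
    archive_line("bob", "forumA", "t1", 1500000100, "hi"),
    archive_line("carol", "forumB", "t2", 1500000200, "hey")
  )
  rec <- read_comment_archive(write_archive_lines(lines))
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_skipped"), 0L)
  expect_equal(rec$author, c("alice", "bob", "carol"))

  broken <- append(lines, "{this is not json", after = 2)
  expect_warning(rec2 <- read_comment_archive(write_archive_lines(broken)),
                 "skipped 1")
  expect_equal(nrow(rec2), 3)
  expect_equal(attr(rec2, "n_skipped"), 1L)

  # a syntactically valid line missing a mapped field is also skipped
  nofield <- append(lines, '{"author": "dan", "body": "orphan"}', after = 1)
  expect_warning(rec3 <- read_comment_archive(write_archive_lines(nofield)),
                 "skipped 1")
  expect_equal(nrow(rec3), 3)

  expect_error(read_comment_archive(file.path(tempdir(), "nope.jsonl")),
               "does not exist")
})

test_that("schema mapping translates source field names", {
  line <- jsonlite::toJSON(list(who = "alice", board = "forumA",
                                topic = "t9", at = 1500000000, text = "x"),
                           auto_unbox = TRUE)
  rec <- read_comment_archive(
    write_archive_lines(line),
    archive_schema(author = "who", forum = "board", thread_id = "topic",
                   created_utc = "at", body = "text"))
  expect_equal(rec$forum, "forumA")
  expect_equal(rec$thread_id, "t9")
})

test_that("window filtering is month-inclusive and drops excluded accounts", {
  rec <- tibble::tibble(
    author = c("alice", "AutoModerator", "[deleted]", "bob", "carol", "dan"),
    forum = "f",
    thread_id = "t",
    created_utc = c(utc("2017-03-01 00:00:00"), utc("2017-06-15 12:00:00"),
                    utc("2017-06-15 12:00:00"), utc("2018-02-28 23:59:59"),
                    utc("2017-02-28 23:59:59"), utc("2018-03-01 00:00:00")),
    body = "x"
  )
  kept <- filter_records(rec, "2017-03", "2018-02")
  # boundary seconds retained, both placeholders and out-of-window dropped
  expect_setequal(kept$author, c("alice", "bob"))
  # exclusion is exact and case-sensitive
  rec2 <- rec
  rec2$author[2] <- "automoderator"
  expect_true("automoderator" %in%
                filter_records(rec2, "2017-03", "2018-02")$author)
  expect_error(filter_records(rec, "2018-02", "2017-03"), "precedes")
})

test_that("filtering is idempotent and synthetic counts match ground truth", {
  gen <- generate_archive(generator_config(n_commenters = 150, seed = 3))
  rec <- gen$records
  once <- filter_records(rec, "2017-03", "2018-02")
  twice <- filter_records(once, "2017-03", "2018-02")
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_equal(nrow(rec), gen$ground_truth$n_records)
  # excluded accounts never survive into any downstream structure
  idx <- build_indices(once)
  expect_false(any(default_excluded_authors() %in%
                     unlist(idx$commenters, use.names = FALSE)))
})

test_that("forum discovery matches terms, drops private and excluded names", {
  meta <- tibble::tibble(
    name = c("anorexiahelp", "Anorexiclizardpeople", "bulimiasupport",
             "privateana", "cooking"),
    description = c("support forum", "lizard memes", "bulimia recovery",
                    "anorexia talk", "recipes and food"),
    is_private = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  got <- discover_forums(meta, c("anorexi", "bulimia"),
                         manual_exclusions = "Anorexiclizardpeople")
  expect_equal(got, c("anorexiahelp", "bulimiasupport"))
  expect_equal(discover_forums(meta, "zzzz"), character(0))
  # description matching and case-insensitivity
  expect_true("cooking" %in% discover_forums(meta, "RECIPES"))
})

test_that("minimum-commenter threshold is strict on 'fewer than'", {
  idx <- list(
    small = sprintf("u%03d", 1:499),
    exact = sprintf("v%03d", 1:500),
    big = sprintf("w%04d", 1:5000)
  )
  expect_setequal(apply_min_commenter_threshold(idx, 500), c("exact", "big"))
  expect_setequal(apply_min_commenter_threshold(idx, 1),
                  c("small", "exact", "big"))
})

test_that("indices are mutually consistent and honour the whitelist", {
  rec <- tibble::tibble(
    author = c("a", "a", "b", "c"),
    forum = c("f1", "f2", "f1", "f3"),
    thread_id = c("t1", "t2", "t1", "t3"),
    created_utc = utc("2017-05-01 00:00:00") + 0:3,
    body = "x"
  )
  idx <- build_indices(rec)
  expect_equal(idx$commenters, list(f1 = c("a", "b"), f2 = "a", f3 = "c"))
  expect_equal(nrow(idx$threads), 4)
  # distinct (forum, thread) pairs equal per-forum thread counts
  expect_equal(nrow(unique(idx$threads[, c("forum", "thread_id")])), 3)
  idx2 <- build_indices(rec, forum_whitelist = c("f1", "f2"))
  expect_named(idx2$commenters, c("f1", "f2"))

  gen <- generate_archive(generator_config(n_commenters = 200, seed = 8))
  filtered <- filter_records(gen$records, "2017-03", "2018-02")
  got <- build_indices(filtered)$commenters
  expect_equal(got, gen$ground_truth$commenter_sets)
})

test_that("index CSV export round-trips the commenter pairs", {
  rec <- tibble::tibble(
    author = c("a", "b", "a"), forum = c("f1", "f1", "f2"),
    thread_id = c("t1", "t1", "t2"),
    created_utc = utc("2017-05-01 00:00:00") + 0:2, body = "x"
  )
  idx <- build_indices(rec)
  cp <- withr::local_tempfile(fileext = ".csv")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_indices(idx, cp, tp)
  pairs <- utils::read.csv(cp)
  expect_equal(nrow(pairs), 3)
  counts <- utils::read.csv(tp)
  expect_equal(counts$n_comments[counts$forum == "f1"], 2)
})
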