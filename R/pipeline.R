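#' Pipeline configuration
#'
#' Collects every tunable of the two-stage analysis in one declarative
#' object. Defaults are the study conditions of the methodology:
#' a 500-commenter forum floor, the five recovery terms, walk length 4,
#' a 1% ancillary inclusion rule, top-50 ancillary selection, and a
#' 1000-commenter subtype floor.
#'
#' @param archive Path to the JSON-lines comment archive.
#' @param output_dir Directory for all written artifacts.
#' @param forum_meta Optional path to the forum metadata CSV (`name`,
#'   `description`, `is_private`); when given, forum discovery by search
#'   term is applied before indexing.
#' @param window_start,window_end Calendar-month window (`"YYYY-MM"`).
#' @param excluded_authors Accounts dropped from all analyses.
#' @param search_terms Terms for forum discovery (used with `forum_meta`).
#' @param manual_exclusions Forum names excluded by manual review.
#' @param min_commenters Forum inclusion floor (distinct commenters).
#' @param recovery_terms Terms for the recovery-focus statistic.
#' @param walk_length Walktrap walk length t.
#' @param min_weight Exclusive edge threshold for graph construction.
#' @param ancillary_inclusion Ancillary inclusion fraction.
#' @param top_k Ancillary forums selected per subtype.
#' @param min_subtype_commenters Subtype floor for profiling.
#' @param seed Seed recorded with the run (the analysis itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(archive, output_dir,
                            forum_meta = NULL,
                            window_start = "2017-03",
                            window_end = "2018-02",
                            excluded_authors = default_excluded_authors(),
                            search_terms = character(),
                            manual_exclusions = character(),
                            min_commenters = 500,
                            recovery_terms = forumnet::recovery_terms(),
                            walk_length = 4,
                            min_weight = 0,
                            ancillary_inclusion = 0.01,
                            top_k = 50,
                            min_subtype_commenters = 1000,
                            seed = 1) {
  cfg <- list(archive = archive, output_dir = output_dir,
              forum_meta = forum_meta, window_start = window_start,
              window_end = window_end, excluded_authors = excluded_authors,
              search_terms = search_terms,
              manual_exclusions = manual_exclusions,
              min_commenters = min_commenters,
              recovery_terms = recovery_terms, walk_length = walk_length,
              min_weight = min_weight,
              ancillary_inclusion = ancillary_inclusion, top_k = top_k,
              min_subtype_commenters = min_subtype_commenters, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly: writing and re-reading reproduces the
#' configuration.
#'
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML has no empty character vector; restore the type
  for (f in c("excluded_authors", "search_terms", "manual_exclusions",
              "recovery_terms")) {
    if (f %in% names(raw)) raw[[f]] <- as.character(unlist(raw[[f]]))
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

make_logger <- function(log_path) {
  function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_partition_csv <- function(partition, path) {
  utils::write.csv(
    data.frame(forum = names(partition$membership),
               community = as.integer(partition$membership)),
    path, row.names = FALSE)
}

write_venn_csv <- function(venn, path) {
  df <- as.data.frame(venn[, c("region", "n_communities", "count")])
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run forum subtype discovery (objective 1)
#'
#' End-to-end driver: ingest and filter the archive, (optionally) discover
#' forums by search term, apply the minimum-commenter floor, build the
#' mean commenter-overlap network, detect communities, compute the
#' recovery-focus report and the community-level commenter overlap, and
#' write all artifacts plus a run log to the output directory. The manual
#' review step is represented by `labels_stub.tsv` — an editable file
#' joining each forum to its detected community and an empty free-text
#' subtype label.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the indices, retained forums, overlap
#'   matrix, graph, dendrogram, partition, recovery report, community
#'   sets, Venn regions and bot report.
#' @export
run_subtype_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  log <- make_logger(out("run.log"))
  log("subtype discovery started (archive: %s)", config$archive)

  records <- run_stage("ingest", read_comment_archive(config$archive))
  log("records read: %d (skipped lines: %d)", nrow(records),
      attr(records, "n_skipped"))
  records <- run_stage("filter", filter_records(
    records, config$window_start, config$window_end,
    config$excluded_authors))
  log("records in window after exclusions: %d", nrow(records))

  whitelist <- NULL
  if (!is.null(config$forum_meta)) {
    meta <- run_stage("forum discovery", read_forum_meta(config$forum_meta))
    whitelist <- run_stage("forum discovery", discover_forums(
      meta, config$search_terms, config$manual_exclusions))
    log("forums matching search terms: %d", length(whitelist))
  }
  indices <- run_stage("indexing", build_indices(records, whitelist))
  forums <- run_stage("commenter threshold", apply_min_commenter_threshold(
    indices$commenters, config$min_commenters))
  log("forums with >= %d commenters: %d", config$min_commenters,
      length(forums))
  if (length(forums) == 0) {
    stop("stage 'commenter threshold' failed: no forum reaches the ",
         "minimum-commenter floor; nothing to analyse", call. = FALSE)
  }

  matrix <- run_stage("overlap matrix",
                      build_overlap_matrix(indices$commenters, forums))
  graph <- run_stage("network", matrix_to_graph(matrix, config$min_weight))
  dendrogram <- run_stage("community detection",
                          walktrap_dendrogram(graph, config$walk_length))
  partition <- run_stage("community detection",
                         best_partition(dendrogram, graph))
  log("communities detected: %d (modularity %.4f)",
      partition$n_communities, partition$modularity)
  recovery <- run_stage("text mining", recovery_focus(
    indices$threads, config$recovery_terms, forums))
  comm_sets <- run_stage("community overlap",
                         community_commenter_sets(partition,
                                                  indices$commenters))
  venn <- run_stage("community overlap", venn_partition(comm_sets))
  activity <- table(records$author[records$forum %in% forums])
  bot <- run_stage("bot report", bot_name_report(
    stats::setNames(as.numeric(activity), names(activity))))
  log("commenters across retained forums: %d (bot-named: %d, %.2f%%)",
      bot$n_total, bot$n_flagged, bot$fraction_percentage)

  write_indices(indices, out("commenter_index.csv"), out("thread_counts.csv"))
  write_overlap_matrix(matrix, out("overlap_matrix.csv"))
  write_graphml(graph, out("network.graphml"))
  utils::write.csv(dendrogram$merges, out("dendrogram.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(modularity_curve(dendrogram, graph)),
                   out("modularity_curve.csv"), row.names = FALSE)
  write_partition_csv(partition, out("partition.csv"))
  utils::write.csv(as.data.frame(recovery), out("recovery_report.csv"),
                   row.names = FALSE)
  write_venn_csv(venn, out("venn_regions.csv"))
  stub <- data.frame(forum = names(partition$membership),
                     community = as.integer(partition$membership),
                     label = "")
  utils::write.table(stub, out("labels_stub.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_forums = length(forums), n_commenters = bot$n_total,
         n_communities = partition$n_communities,
         modularity = partition$modularity,
         bot_fraction_percentage = bot$fraction_percentage,
         universe_size = attr(venn, "universe_size")),
    out("summary.json"), auto_unbox = TRUE, digits = NA)
  log("subtype discovery finished")

  invisible(list(records = records, indices = indices, forums = forums,
                 matrix = matrix, graph = graph, dendrogram = dendrogram,
                 partition = partition, recovery = recovery,
                 community_sets = comm_sets, venn = venn, bot = bot))
}

#' Profile subtype commenters by ancillary forums (objective 2)
#'
#' For each labelled subtype with at least the configured commenter floor:
#' identify ancillary forum candidates under the 1% rule, dual-rank them,
#' select the top K, build the overlap network restricted to the
#' subtype's commenters, detect communities, and write the ranking,
#' selection, matrices, partition, participation and Venn-region reports
#' to a per-subtype subdirectory.
#'
#' @param config A [pipeline_config()].
#' @param subtype_labels Data frame (`forum`, `subtype`) mapping member
#'   forums to subtype labels (e.g. the edited `labels_stub.tsv`), or the
#'   path of such a tab-separated file. Forums unknown to the archive are
#'   a fatal error.
#' @param indices Optional pre-built [build_indices()] result for the full
#'   archive; read from `config$archive` when omitted.
#' @return Invisibly, a named list (one element per profiled subtype) of
#'   lists with the ranking, selection, restricted matrix, partition,
#'   participation, Venn regions and coverage.
#' @export
run_commenter_profiling <- function(config, subtype_labels,
                                    indices = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- make_logger(file.path(config$output_dir, "profiling.log"))
  if (is.character(subtype_labels)) {
    subtype_labels <- utils::read.delim(subtype_labels,
                                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("forum", "subtype") %in% names(subtype_labels)))

  if (is.null(indices)) {
    records <- run_stage("ingest", read_comment_archive(config$archive))
    records <- run_stage("filter", filter_records(
      records, config$window_start, config$window_end,
      config$excluded_authors))
    indices <- run_stage("indexing", build_indices(records))
  }
  unknown <- setdiff(subtype_labels$forum, names(indices$commenters))
  if (length(unknown) > 0) {
    stop("unknown forum(s) in subtype definitions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  results <- list()
  for (label in unique(subtype_labels$subtype)) {
    members <- subtype_labels$forum[subtype_labels$subtype == label]
    subtype <- subtype_definition(label, members, indices$commenters)
    if (length(subtype$commenters) < config$min_subtype_commenters) {
      log("subtype '%s' skipped: %d commenters < floor of %d", label,
          length(subtype$commenters), config$min_subtype_commenters)
      next
    }
    log("profiling subtype '%s': %d forums, %d commenters", label,
        length(members), length(subtype$commenters))
    sdir <- file.path(config$output_dir,
                      gsub("[^A-Za-z0-9_-]", "_", label))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(sdir, f)

    candidates <- run_stage("ancillary candidates", find_ancillary_forums(
      indices$commenters, subtype, config$ancillary_inclusion))
    log("  ancillary candidates above the %.2g%% rule: %d",
        100 * config$ancillary_inclusion, nrow(candidates))
    if (nrow(candidates) == 0) {
      log("  subtype '%s' skipped: no ancillary candidates", label)
      next
    }
    ranking <- run_stage("ranking", rank_ancillary_forums(candidates))
    selection <- run_stage("selection", select_top_k(ranking, config$top_k))
    matrix <- run_stage("restricted overlap", restricted_overlap_matrix(
      indices$commenters, selection, subtype$commenters))
    graph <- run_stage("network", matrix_to_graph(matrix, config$min_weight))
    dendrogram <- run_stage("community detection",
                            walktrap_dendrogram(graph, config$walk_length))
    partition <- run_stage("community detection",
                           best_partition(dendrogram, graph))
    log("  communities detected: %d (modularity %.4f)",
        partition$n_communities, partition$modularity)
    restricted_sets <- lapply(indices$commenters[selection], intersect,
                              y = subtype$commenters)
    comm_sets <- run_stage("community overlap", community_commenter_sets(
      partition, restricted_sets))
    universe <- unique(unlist(comm_sets, use.names = FALSE))
    participation <- run_stage("community overlap",
                               community_participation(comm_sets, universe))
    venn <- run_stage("community overlap", venn_partition(comm_sets))
    cov <- run_stage("coverage", coverage(subtype$commenters,
                                          restricted_sets))
    log("  coverage: %.2f%% (%d/%d) of subtype commenters on selected forums",
        cov$percentage, cov$n_covered, cov$n_subtype)

    utils::write.table(as.data.frame(ranking), out("ranking.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(selection, out("selection.txt"))
    write_overlap_matrix(matrix, out("restricted_matrix.csv"))
    write_graphml(graph, out("network.graphml"))
    write_partition_csv(partition, out("partition.csv"))
    utils::write.csv(as.data.frame(participation), out("participation.csv"),
                     row.names = FALSE)
    write_venn_csv(venn, out("venn_regions.csv"))
    jsonlite::write_json(
      list(subtype = label, n_commenters = length(subtype$commenters),
           n_candidates = nrow(candidates), n_selected = length(selection),
           n_communities = partition$n_communities,
           modularity = partition$modularity,
           coverage_percentage = cov$percentage,
           coverage_n = cov$n_covered),
      out("summary.json"), auto_unbox = TRUE, digits = NA)

    results[[label]] <- list(subtype = subtype, candidates = candidates,
                             ranking = ranking, selection = selection,
                             matrix = matrix, graph = graph,
                             partition = partition,
                             community_sets = comm_sets,
                             participation = participation, venn = venn,
                             coverage = cov)
  }
  log("profiling finished: %d subtype(s) profiled", length(results))
  invisible(results)
}
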