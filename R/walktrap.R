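#' Walktrap agglomerative dendrogram
#'
#' Community detection for weighted undirected graphs by short random
#' walks. A t-step random walk started at a node tends to stay inside that
#' node's community, so nodes with similar t-step visit distributions are
#' structurally close. The method:
#'
#' 1. each vertex receives a self-loop weighted by the mean of its
#'    incident edge weights (the reference implementation's device for
#'    making the walk aperiodic), then transition probabilities are
#'    proportional to incident edge weights, `P_ij = w_ij / s_i` with
#'    `s_i` the weighted degree;
#' 2. node distance `r_ij`: Euclidean distance between t-step walk
#'    distributions, each coordinate normalized by the destination's
#'    weighted degree;
#' 3. agglomeration from singletons, merging only adjacent communities,
#'    at each step performing the merge with the smallest Ward-style
#'    increase in mean squared walk distance; a merged community's walk
#'    distribution is the member average;
#' 4. ties broken by the lexicographically smallest community-id pair,
#'    so results are reproducible across platforms.
#'
#' A disconnected graph is processed one connected component at a time and
#' the merge lists concatenated; the component count is kept in the result.
#'
#' @param graph Weighted undirected igraph graph; all weights must be
#'   positive (an unweighted graph is treated as unit weights).
#' @param t Walk length in steps (default 4, the customary choice for
#'   networks of up to a few thousand nodes).
#' @return An object of class `walktrap_dendrogram`: list with `merges`
#'   (data frame `left`, `right`, `new_id`, `delta_sigma`; leaves are ids
#'   `1..n` in vertex order, internal nodes `n+1, ...`), `n`, `labels`,
#'   `n_components` and `t`.
#' @seealso [best_partition()], [graph_modularity()]
#' @export
walktrap_dendrogram <- function(graph, t = 4) {
  stopifnot(igraph::is_igraph(graph), t >= 1)
  if (igraph::is_directed(graph)) {
    stop("walktrap requires an undirected graph", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  if (any(w <= 0)) {
    stop("all edge weights must be strictly positive", call. = FALSE)
  }
  labels <- igraph::V(graph)$name
  if (is.null(labels)) labels <- as.character(seq_len(n))

  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr =
    if (!is.null(igraph::E(graph)$weight)) "weight" else NULL,
    sparse = FALSE))
  comp <- igraph::components(graph)

  merges <- data.frame(left = integer(), right = integer(),
                       new_id = integer(), delta_sigma = double())
  next_id <- n + 1
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    cm <- walktrap_component(A[vs, vs, drop = FALSE], t)
    if (nrow(cm) > 0) {
      # map local ids to global: leaves -> vertex indices, internal -> fresh
      n_local <- length(vs)
      id_map <- as.integer(c(vs, seq(next_id, length.out = n_local - 1)))
      merges <- rbind(merges, data.frame(
        left = id_map[cm$left], right = id_map[cm$right],
        new_id = id_map[cm$new_id], delta_sigma = cm$delta_sigma
      ))
      next_id <- next_id + (n_local - 1)
    }
  }
  structure(
    list(merges = merges, n = n, labels = labels,
         n_components = comp$no, t = t),
    class = "walktrap_dendrogram"
  )
}

# Agglomeration within one connected component. A: weighted adjacency
# (local indices, zero diagonal); returns merges in local ids (leaves
# 1..n_local).
walktrap_component <- function(A, t) {
  n <- nrow(A)
  empty <- data.frame(left = integer(), right = integer(),
                      new_id = integer(), delta_sigma = double())
  if (n == 1) return(empty)
  # self-loop per vertex equal to its mean incident edge weight: makes the
  # walk aperiodic without letting high-degree vertices dominate; the
  # convention of the published algorithm's reference implementation
  diag(A) <- 0
  adjacency <- A > 0
  diag(A) <- rowSums(A) / rowSums(adjacency)
  d <- rowSums(A)
  P <- A / d
  Pt <- P
  if (t > 1) for (i in seq_len(t - 1)) Pt <- Pt %*% P

  n_ids <- 2 * n - 1
  dist <- matrix(NA_real_, n_ids, n)     # community walk distributions
  dist[1:n, ] <- Pt
  size <- integer(n_ids); size[1:n] <- 1L
  adj <- matrix(FALSE, n_ids, n_ids)
  adj[1:n, 1:n] <- adjacency
  diag(adj) <- FALSE
  active <- c(rep(TRUE, n), rep(FALSE, n - 1))

  delta_sigma <- function(i, j) {
    r2 <- sum((dist[i, ] - dist[j, ])^2 / d)
    (size[i] * size[j]) / (size[i] + size[j]) * r2 / n
  }

  out <- empty
  for (step in seq_len(n - 1)) {
    ids <- which(active)
    best <- NULL
    best_ds <- Inf
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        i <- ids[a]; j <- ids[b]
        if (!adj[i, j]) next
        ds <- delta_sigma(i, j)
        # relative tolerance so exact symmetric ties resolve toward the
        # lexicographically smallest pair (the first one enumerated)
        if (is.null(best) || ds < best_ds * (1 - 1e-12)) {
          best_ds <- ds
          best <- c(i, j)
        }
      }
    }
    new_id <- n + step
    i <- best[1]; j <- best[2]
    dist[new_id, ] <- (size[i] * dist[i, ] + size[j] * dist[j, ]) /
      (size[i] + size[j])
    size[new_id] <- size[i] + size[j]
    adj[new_id, ] <- adj[i, ] | adj[j, ]
    adj[, new_id] <- adj[new_id, ]
    adj[new_id, c(i, j)] <- FALSE
    adj[c(i, j), new_id] <- FALSE
    adj[new_id, new_id] <- FALSE
    active[c(i, j)] <- FALSE
    active[new_id] <- TRUE
    out <- rbind(out, data.frame(left = i, right = j, new_id = new_id,
                                 delta_sigma = best_ds))
  }
  out
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) [c_i == c_j]`, with `s` the
#' weighted degree and `m` the total edge weight: the fraction of edge
#' weight falling within communities minus its expectation under a
#' degree-preserving null model. Lies in \[-0.5, 1\].
#'
#' @param graph Weighted undirected igraph graph.
#' @param membership Community labels for every vertex, in vertex order
#'   (or named by vertex name).
#' @return The modularity score Q.
#' @export
graph_modularity <- function(graph, membership) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (!is.null(names(membership)) && !is.null(nm)) {
    if (!all(nm %in% names(membership))) {
      stop("vertex missing from partition: ",
           paste(setdiff(nm, names(membership)), collapse = ", "),
           call. = FALSE)
    }
    membership <- membership[nm]
  }
  if (length(membership) != n || anyNA(membership)) {
    stop("partition must label every vertex exactly once", call. = FALSE)
  }
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr =
    if (!is.null(igraph::E(graph)$weight)) "weight" else NULL,
    sparse = FALSE))
  two_m <- sum(A)
  if (two_m == 0) return(0)
  s <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    q <- q + sum(A[idx, idx]) / two_m - (sum(s[idx]) / two_m)^2
  }
  q
}

# Membership vector (labels 1..k by first appearance) after applying the
# first `level` merges of a dendrogram.
cut_membership <- function(dendrogram, level) {
  n <- dendrogram$n
  # union-find over dendrogram ids
  parent <- seq_len(n + nrow(dendrogram$merges))
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (level > 0) {
    for (r in seq_len(level)) {
      m <- dendrogram$merges[r, ]
      parent[find(m$left)] <- m$new_id
      parent[find(m$right)] <- m$new_id
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  names(labels) <- dendrogram$labels
  labels
}

#' Modularity across all dendrogram cut levels
#'
#' @param dendrogram A [walktrap_dendrogram()] result.
#' @param graph The graph the dendrogram was built from.
#' @return A tibble with one row per cut level (0 = all singletons):
#'   `level`, `n_communities`, `modularity`.
#' @export
modularity_curve <- function(dendrogram, graph) {
  levels <- 0:nrow(dendrogram$merges)
  rows <- lapply(levels, function(l) {
    mem <- cut_membership(dendrogram, l)
    tibble::tibble(level = l, n_communities = length(unique(mem)),
                   modularity = graph_modularity(graph, mem))
  })
  do.call(rbind, rows)
}

#' Modularity-optimal partition of a walktrap dendrogram
#'
#' Evaluates the weighted modularity of the partition at every cut level
#' of the dendrogram and returns the maximum; among equal-modularity cuts
#' the one with fewer communities is preferred.
#'
#' @param dendrogram A [walktrap_dendrogram()] result.
#' @param graph The graph the dendrogram was built from.
#' @return An object of class `forum_partition`: list with `membership`
#'   (named integer vector, contiguous labels from 1), `n_communities`,
#'   `modularity` and `level`.
#' @export
best_partition <- function(dendrogram, graph) {
  curve <- modularity_curve(dendrogram, graph)
  best_q <- max(curve$modularity)
  # ties (within numerical noise) resolved toward fewer communities,
  # i.e. the deepest qualifying cut
  cand <- which(curve$modularity >= best_q - 1e-12)
  level <- curve$level[max(cand)]
  mem <- cut_membership(dendrogram, level)
  structure(
    list(membership = mem, n_communities = length(unique(mem)),
         modularity = curve$modularity[curve$level == level], level = level),
    class = "forum_partition"
  )
}

#' Walktrap communities of a graph
#'
#' Convenience wrapper: [walktrap_dendrogram()] followed by
#' [best_partition()].
#'
#' @inheritParams walktrap_dendrogram
#' @return A `forum_partition` (see [best_partition()]).
#' @export
walktrap_communities <- function(graph, t = 4) {
  best_partition(walktrap_dendrogram(graph, t), graph)
}

#' @export
print.forum_partition <- function(x, ...) {
  cat(sprintf("forum partition: %d communities, modularity %.4f\n",
              x$n_communities, x$modularity))
  for (c in sort(unique(x$membership))) {
    cat(sprintf("  [%d] %s\n", c,
                paste(names(x$membership)[x$membership == c],
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.walktrap_dendrogram <- function(x, ...) {
  cat(sprintf("walktrap dendrogram: %d nodes, %d merges, %d component(s), t = %d\n",
              x$n, nrow(x$merges), x$n_components, x$t))
  invisible(x)
}

#' Community commenter sets of a partition
#'
#' For each community of a forum partition, the union of its member
#' forums' commenter sets.
#'
#' @param partition A `forum_partition` over forum names.
#' @param commenter_index Named list, forum -> commenter set.
#' @return Named list, community label (as character) -> commenter set.
#' @export
community_commenter_sets <- function(partition, commenter_index) {
  forums <- names(partition$membership)
  missing <- setdiff(forums, names(commenter_index))
  if (length(missing) > 0) {
    stop("forum(s) missing from commenter index: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(forums, partition$membership), function(fs) {
    sort(unique(unlist(commenter_index[fs], use.names = FALSE)))
  })
  names(out) <- as.character(names(out))
  out
}
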