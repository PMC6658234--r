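#' Mean commenter overlap between two forums
#'
#' For commenter sets A and B, the mean of the two directed proportions
#' `|A n B| / |A|` and `|A n B| / |B|`. Averaging the two directions
#' accounts for differences in forum size: a forum of 100 commenters
#' sharing 40 with a forum of 50 commenters gives (0.4 + 0.8) / 2 = 0.6.
#'
#' @param set_a,set_b Non-empty character vectors of commenter names
#'   (duplicates are ignored).
#' @return The mean overlap, a number in \[0, 1\]; symmetric in its
#'   arguments.
#' @export
#' @examples
#' a <- paste0("u", 1:100)
#' b <- paste0("u", 61:110)
#' pairwise_mean_overlap(a, b) # 0.6
pairwise_mean_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("mean overlap is undefined for an empty commenter set",
         call. = FALSE)
  }
  shared <- length(intersect(a, b))
  (shared / length(a) + shared / length(b)) / 2
}

#' Build the pairwise mean-overlap matrix
#'
#' Fills a symmetric forum-by-forum matrix with the mean commenter overlap
#' of every unordered pair. The diagonal is zero by convention: a forum's
#' overlap with itself is not an edge of the network.
#'
#' @param commenter_index Named list, forum -> commenter set.
#' @param forums Character vector of forum names to include (row/column
#'   order of the result).
#' @return A symmetric numeric matrix with `forums` as dimnames, entries
#'   in \[0, 1\], zero diagonal.
#' @export
build_overlap_matrix <- function(commenter_index, forums) {
  stopifnot(length(forums) >= 1)
  missing <- setdiff(forums, names(commenter_index))
  if (length(missing) > 0) {
    stop("forum(s) missing from commenter index: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(commenter_index[forums], unique)
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    stop("forum(s) with empty commenter set: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  n <- length(forums)
  m <- matrix(0, n, n, dimnames = list(forums, forums))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        w <- pairwise_mean_overlap(sets[[i]], sets[[j]])
        m[i, j] <- w
        m[j, i] <- w
      }
    }
  }
  m
}

validate_overlap_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            !is.null(rownames(matrix)))
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("overlap matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(matrix) != 0)) {
    stop("overlap matrix diagonal must be zero", call. = FALSE)
  }
  if (any(matrix < 0) || any(matrix > 1)) {
    stop("overlap weights must lie in [0, 1]", call. = FALSE)
  }
  invisible(matrix)
}

#' Convert an overlap matrix to a weighted undirected graph
#'
#' Creates an edge for every off-diagonal cell strictly greater than
#' `min_weight`; isolated forums keep their node. The analysis default is
#' `min_weight = 0` (no pruning before community detection); a positive
#' threshold is exposed for sensitivity analysis and display.
#'
#' @param matrix Symmetric overlap matrix from [build_overlap_matrix()].
#' @param min_weight Exclusive edge-weight threshold (default 0).
#' @return An [igraph][igraph::graph_from_adjacency_matrix] weighted
#'   undirected graph whose vertex names are the forum labels.
#' @export
matrix_to_graph <- function(matrix, min_weight = 0) {
  validate_overlap_matrix(matrix)
  m <- matrix
  m[m <= min_weight] <- 0
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Write an overlap matrix as CSV
#'
#' @param matrix Overlap matrix.
#' @param path Output path; forum names form the header row and first
#'   column.
#' @return Invisibly, `path`.
#' @export
write_overlap_matrix <- function(matrix, path) {
  validate_overlap_matrix(matrix)
  utils::write.csv(as.data.frame(matrix), path, row.names = TRUE)
  invisible(path)
}

#' Read an overlap matrix written by [write_overlap_matrix()]
#'
#' @param path CSV path.
#' @return The overlap matrix.
#' @export
read_overlap_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- rownames(m)
  validate_overlap_matrix(m)
  m
}

#' Export a forum graph as GraphML
#'
#' Writes the graph with its `weight` edge attribute, readable by standard
#' network tools.
#'
#' @param graph igraph graph from [matrix_to_graph()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
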