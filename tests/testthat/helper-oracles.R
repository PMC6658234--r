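# independent oracles and fixture builders used across the suite

# random commenter sets drawn from a shared pool
random_sets <- function(n_sets, pool_size = 60, min_size = 3,
                        max_size = 30) {
  pool <- sprintf("u%04d", seq_len(pool_size))
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(pool, sample(min_size:max_size, 1))
  })
  names(sets) <- sprintf("forum%02d", seq_len(n_sets))
  sets
}

# brute-force mean overlap straight from the set algebra
oracle_mean_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- sum(a %in% b)
  (i / length(a) + i / length(b)) / 2
}

# weighted graph from a dense symmetric matrix
graph_from_matrix <- function(m) {
  igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# two k-cliques (unit weights) joined by one bridge edge
barbell_graph <- function(k = 4, bridge_weight = 0.1) {
  n <- 2 * k
  m <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  m[1:k, 1:k] <- 1
  m[(k + 1):n, (k + 1):n] <- 1
  diag(m) <- 0
  m[k, k + 1] <- m[k + 1, k] <- bridge_weight
  graph_from_matrix(m)
}

# random connected weighted graph (no planted structure)
random_weighted_graph <- function(n, p = 0.5, wmin = 0.05, wmax = 1) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), wmin, wmax)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# random connected weighted graph with two planted blocks
planted_block_graph <- function(n, p_in = 0.9, p_out = 0.25,
                                w_in = c(0.5, 1), w_out = c(0.05, 0.3)) {
  repeat {
    block <- rep(1:2, length.out = n)
    m <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      same <- block[i] == block[j]
      if (stats::runif(1) < (if (same) p_in else p_out)) {
        w <- if (same) stats::runif(1, w_in[1], w_in[2])
             else stats::runif(1, w_out[1], w_out[2])
        m[i, j] <- m[j, i] <- w
      }
    }
    rownames(m) <- colnames(m) <- paste0("v", seq_len(n))
    g <- graph_from_matrix(m)
    if (igraph::is_connected(g)) return(list(graph = g, block = block))
  }
}

# brute-force weighted modularity by the double sum over all vertex pairs
oracle_modularity <- function(graph, membership) {
  a <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = FALSE))
  two_m <- sum(a)
  s <- unname(rowSums(a))
  q <- 0
  n <- nrow(a)
  for (i in 1:n) for (j in 1:n) {
    if (membership[i] == membership[j]) {
      q <- q + a[i, j] - s[i] * s[j] / two_m
    }
  }
  q / two_m
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (lab in seq_len(next_label)) {
      rec(c(assign, lab), max(next_label, lab + 1))
    }
  }
  rec(integer(0), 1)
  out
}

# exhaustive maximum-modularity partition for small graphs
oracle_best_partition <- function(graph) {
  n <- igraph::vcount(graph)
  parts <- all_partitions(n)
  qs <- vapply(parts, function(p) oracle_modularity(graph, p), numeric(1))
  best <- which.max(qs)
  list(membership = parts[[best]], modularity = qs[best])
}

# write a JSON-lines fixture archive from raw lines
write_archive_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".jsonl",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

archive_line <- function(author, subreddit, link_id, created_utc, body) {
  jsonlite::toJSON(
    list(author = author, subreddit = subreddit, link_id = link_id,
         created_utc = created_utc, body = body),
    auto_unbox = TRUE)
}

# timestamp helper: seconds since epoch for a UTC date-time string
utc <- function(s) as.numeric(as.POSIXct(s, tz = "UTC"))
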