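# Independent oracles used across the suite. These are deliberately naive
# (dynamic programming, dense matrix powers, exhaustive enumeration) and
# share no code with the package internals they check.

# Full dynamic-programming Levenshtein distance over symbol sequences.
dp_levenshtein <- function(a, b) {
  la <- length(a); lb <- length(b)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[la + 1L, lb + 1L]
}

# Dense transition matrix of one spreading step: a' = (1-d) (r I + (1-r) W) a
# with W[i, j] = A[i, j] / deg(j) (and zero columns for degree-0 nodes).
spread_matrix <- function(graph, retention, decay) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  deg <- colSums(A)
  W <- sweep(A, 2L, ifelse(deg > 0, deg, 1), "/")
  W[, deg == 0] <- 0
  (1 - decay) * (retention * diag(nrow(A)) + (1 - retention) * W)
}

# t-step final state by explicit matrix power.
spread_by_matrix_power <- function(graph, init, retention, decay, t) {
  M <- spread_matrix(graph, retention, decay)
  a <- init
  for (k in seq_len(t)) a <- M %*% a
  as.numeric(a)
}

# Mean local clustering by per-node triangle enumeration.
brute_avg_clustering <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2L) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

# Mean shortest path length over unordered pairs, by repeated BFS.
brute_aspl <- function(graph) {
  n <- igraph::vcount(graph)
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  total <- 0; pairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1)) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    total <- total + sum(dist[-s])
    pairs <- pairs + (n - 1L)
  }
  total / pairs
}

# Newman-Girvan modularity of a membership vector, from first principles.
brute_modularity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(graph)
  q <- 0
  same <- membership[el[, 1L]] == membership[el[, 2L]]
  q <- sum(same) / m
  for (com in unique(membership)) {
    q <- q - (sum(deg[membership == com]) / (2 * m))^2
  }
  q
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxc) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return()
    }
    for (c in seq_len(maxc + 1L)) {
      rec(c(assign, c), max(maxc, c))
    }
  }
  rec(integer(0), 0L)
  out
}

# Maximum modularity over all partitions (exhaustive; n <= ~8).
best_modularity <- function(graph) {
  parts <- all_partitions(igraph::vcount(graph))
  best <- -Inf; best_part <- NULL
  for (p in parts) {
    q <- brute_modularity(graph, p)
    if (q > best) { best <- q; best_part <- p }
  }
  list(modularity = best, membership = best_part)
}

# Random phoneme lexicon for oracle comparisons (distinct from the
# package's calibrated generator).
random_fixture_lexicon <- function(n, inventory = letters[1:6],
                                   lengths = 1:5, seed = 1) {
  set.seed(seed)
  trans <- character(0)
  while (length(trans) < n) {
    L <- sample(lengths, 1L)
    trans <- unique(c(trans, paste(sample(inventory, L, replace = TRUE),
                                   collapse = "")))
  }
  phon_lexicon(word = paste0("w", seq_len(n)), transcription = trans[seq_len(n)],
               scheme = "chars")
}

# Small Erdos-Renyi graph with named vertices.
random_named_graph <- function(n, p, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}
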