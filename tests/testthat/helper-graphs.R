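# Graph fixtures and oracles: exhaustive modularity search, random
# graphs, planted two-block graphs, adjusted Rand index.

graph_from_adjacency <- function(A, nodes = NULL) {
  # build a tf_graph from an undirected 0/1 adjacency matrix, routing
  # each upper-triangle edge once as a "mention"
  n <- nrow(A)
  if (is.null(nodes)) nodes <- sprintf("n%02d", seq_len(n))
  src <- c(); dst <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && A[i, j] > 0) {
      src <- c(src, nodes[i]); dst <- c(dst, nodes[j])
    }
  }
  tweets <- tweet_tbl(
    tweet_id = c(sprintf("s%02d", seq_len(n)),
                 sprintf("e%03d", seq_along(src))),
    author_id = c(nodes, src),
    mention_ids = c(rep(list(character()), n), as.list(dst))
  )
  build_graph(tweets)
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  res <- list()
  rg <- integer(n)
  gen <- function(i, maxv) {
    if (i > n) {
      res[[length(res) + 1]] <<- rg[seq_len(n)]
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) {
      rg[i] <<- v
      gen(i + 1, max(maxv, v))
    }
  }
  gen(1, 0)
  res
}

modularity_of <- function(A, memb) {
  diag(A) <- 0
  m2 <- sum(A)
  if (m2 == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (cl in unique(memb)) {
    inc <- memb == cl
    q <- q + sum(A[inc, inc]) / m2 - (sum(deg[inc]) / m2)^2
  }
  q
}

best_partition_q <- function(A) {
  max(vapply(all_partitions(nrow(A)), function(m) modularity_of(A, m), 0))
}

random_gnp_adj <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(runif(length(up)) < p)
  A + t(A)
}

two_block_adj <- function(n_per_block, p_in, p_out) {
  n <- 2 * n_per_block
  A <- matrix(0, n, n)
  blk <- rep(1:2, each = n_per_block)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    p <- if (blk[i] == blk[j]) p_in else p_out
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  A
}

adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
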