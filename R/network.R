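#' Build the directed interaction graph of a corpus
#'
#' Authors are nodes. Each tweet contributes one directed edge from its
#' author to every mentioned user, plus an edge to the source user if it
#' is a retweet and to the target user if it is a reply. Tweets doing
#' none of these contribute one self-loop at their author (recorded
#' separately from typed edges). Mentioned users who never tweet still
#' become nodes. Parallel interactions accumulate as edge weight.
#'
#' @param tweets a tweet tibble.
#' @return Object of class `tf_graph`: `nodes` (character),
#'   `edges` (tibble `source`, `target`, `type`, `weight` with one row
#'   per distinct typed pair), `self_loops` (named integer: non-
#'   interacting tweet count per author), `n_tweets`.
#' @export
build_graph <- function(tweets) {
  n <- nrow(tweets)
  src <- character(0); dst <- character(0); typ <- character(0)
  if (n > 0L) {
    men_n <- lengths(tweets$mention_ids)
    src <- rep.int(tweets$author_id, men_n)
    dst <- unlist(tweets$mention_ids, use.names = FALSE)
    typ <- rep.int("mention", sum(men_n))
    rt <- tweets$is_retweet
    src <- c(src, tweets$author_id[rt])
    dst <- c(dst, tweets$source_author_id[rt])
    typ <- c(typ, rep.int("retweet", sum(rt)))
    rp <- tweets$is_reply
    src <- c(src, tweets$author_id[rp])
    dst <- c(dst, tweets$reply_to_user_id[rp])
    typ <- c(typ, rep.int("reply", sum(rp)))
    interacting <- men_n > 0L | rt | rp
  } else {
    interacting <- logical(0)
  }
  loop_authors <- tweets$author_id[!interacting]
  self_loops <- table(loop_authors)
  self_loops <- stats::setNames(as.integer(self_loops), names(self_loops))
  edges <- if (length(src)) {
    key <- paste(src, dst, typ, sep = "\r")
    agg <- rowsum(rep(1L, length(key)), key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    tibble::tibble(source = vapply(parts, `[`, "", 1L),
                   target = vapply(parts, `[`, "", 2L),
                   type = vapply(parts, `[`, "", 3L),
                   weight = as.integer(agg[, 1]))
  } else {
    tibble::tibble(source = character(), target = character(),
                   type = character(), weight = integer())
  }
  edges <- edges[order(edges$source, edges$target, edges$type), ]
  nodes <- sort(unique(c(tweets$author_id, edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges, self_loops = self_loops,
                 n_tweets = n),
            class = "tf_graph")
}

#' @export
print.tf_graph <- function(x, ...) {
  cat(sprintf("Interaction graph: %d nodes, %d typed edges, %d self-loop tweets\n",
              length(x$nodes), nrow(x$edges), sum(x$self_loops)))
  invisible(x)
}

# symmetrized weighted adjacency matrix, self-edges removed
symmetric_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges[graph$edges$source != graph$edges$target, ]
  if (nrow(e)) {
    i <- match(e$source, graph$nodes)
    j <- match(e$target, graph$nodes)
    for (k in seq_along(i)) {
      A[i[k], j[k]] <- A[i[k], j[k]] + e$weight[k]
      A[j[k], i[k]] <- A[j[k], i[k]] + e$weight[k]
    }
  }
  A
}

# Greedy agglomerative modularity maximisation (CNM). Starts from
# singletons, repeatedly merges the connected cluster pair with the
# largest modularity gain (ties: lexicographically smallest pair of
# cluster ids), and returns the best partition seen along the merge
# path. A cached best-partner per cluster keeps each step near-linear.
cnm_cluster <- function(A) {
  n <- nrow(A)
  diag(A) <- 0
  m2 <- sum(A)
  if (n == 0L) return(list(membership = integer(0), q = 0, degenerate = TRUE))
  if (m2 == 0) {
    return(list(membership = seq_len(n), q = 0, degenerate = TRUE))
  }
  E <- A / m2
  a <- rowSums(E)
  active <- rep(TRUE, n)
  memb <- seq_len(n)
  cur_q <- -sum(a^2)
  best_q <- cur_q
  best_memb <- memb
  best_dq <- rep(-Inf, n)
  best_j <- integer(n)
  recompute_row <- function(i) {
    js <- which(active)
    js <- js[js > i]
    js <- js[E[i, js] > 0]
    if (!length(js)) {
      best_dq[i] <<- -Inf
      best_j[i] <<- 0L
      return(invisible())
    }
    dq <- 2 * (E[i, js] - a[i] * a[js])
    k <- which.max(dq)
    best_dq[i] <<- dq[k]
    best_j[i] <<- js[k]
    invisible()
  }
  for (i in seq_len(n)) recompute_row(i)
  repeat {
    g <- which.max(best_dq)
    if (!is.finite(best_dq[g])) break
    i <- g
    j <- best_j[g]
    dq <- best_dq[g]
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    a[i] <- a[i] + a[j]
    active[j] <- FALSE
    best_dq[j] <- -Inf
    best_j[j] <- 0L
    memb[memb == j] <- i
    cur_q <- cur_q + dq
    if (cur_q > best_q + 1e-12) {
      best_q <- cur_q
      best_memb <- memb
    }
    stale <- which(active & (best_j == i | best_j == j))
    for (k in unique(c(i, stale))) recompute_row(k)
    # new pairs (k, i) for k < i may now beat k's cached best
    ks <- which(active)
    ks <- ks[ks < i]
    ks <- ks[E[ks, i] > 0]
    ks <- setdiff(ks, stale)
    if (length(ks)) {
      cand <- 2 * (E[ks, i] - a[ks] * a[i])
      upd <- cand > best_dq[ks]
      if (any(upd)) {
        best_dq[ks[upd]] <- cand[upd]
        best_j[ks[upd]] <- i
      }
    }
  }
  list(membership = match(best_memb, unique(best_memb)),
       q = best_q, degenerate = FALSE)
}

#' Cluster an interaction graph by greedy modularity maximisation
#'
#' Runs Clauset-Newman-Moore greedy agglomerative modularity
#' maximisation on the symmetrized weighted graph, with self-loops
#' excluded. The merge order is deterministic: among equal modularity
#' gains the lexicographically smallest cluster-id pair merges first.
#' An edgeless graph is degenerate: every node is its own cluster with
#' q = 0.
#'
#' @param graph a `tf_graph`.
#' @return Object of class `tf_partition`: `membership` (named integer,
#'   cluster id per node), `q` (modularity of the returned partition),
#'   `degenerate` flag.
#' @export
cluster_graph <- function(graph) {
  stopifnot(inherits(graph, "tf_graph"))
  if (length(graph$nodes) == 0L) stop("graph has no nodes")
  A <- symmetric_adjacency(graph)
  res <- cnm_cluster(A)
  structure(list(membership = stats::setNames(res$membership, graph$nodes),
                 q = res$q, degenerate = res$degenerate),
            class = "tf_partition")
}

#' @export
print.tf_partition <- function(x, ...) {
  cat(sprintf("Partition: %d clusters, modularity Q = %.4f%s\n",
              length(unique(x$membership)), x$q,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum_c (e_cc - a_c^2) over clusters c, where e_cc is the fraction
#' of (symmetrized, weighted) edges inside cluster c and a_c the
#' fraction of edge ends attached to it. Self-loops are excluded, as in
#' [cluster_graph()].
#'
#' @param graph a `tf_graph`.
#' @param partition a `tf_partition`, or a membership vector named by or
#'   aligned with `graph$nodes`.
#' @return The modularity score.
#' @export
modularity_q <- function(graph, partition) {
  memb <- if (inherits(partition, "tf_partition")) {
    partition$membership
  } else {
    partition
  }
  if (!is.null(names(memb))) memb <- memb[graph$nodes]
  stopifnot(length(memb) == length(graph$nodes), !anyNA(memb))
  e <- graph$edges[graph$edges$source != graph$edges$target, ]
  m <- sum(e$weight)
  if (m == 0) return(0)
  ci <- memb[match(e$source, graph$nodes)]
  cj <- memb[match(e$target, graph$nodes)]
  within <- sum(e$weight[ci == cj]) / m
  ends <- c(match(e$source, graph$nodes), match(e$target, graph$nodes))
  deg <- numeric(length(graph$nodes))
  agg <- rowsum(as.numeric(c(e$weight, e$weight)), ends)
  deg[as.integer(rownames(agg))] <- agg[, 1]
  a_c <- as.numeric(rowsum(deg, memb)) / (2 * m)
  within - sum(a_c^2)
}

#' Numeric summary of an interaction network
#'
#' Structural numbers that proxy the qualitative reading of community
#' networks: overall size, the share of isolates (nodes touching no
#' non-self edge -- users whose tweets neither made nor received any
#' interaction), cluster sizes, and per-cluster hub concentration (the
#' largest within-cluster weighted in-degree divided by the
#' within-cluster edge weight). Clusters whose hub concentration exceeds
#' `hub_threshold` are labelled broadcast-like: most of their
#' interaction points at a single account, the hub-and-spoke pattern.
#'
#' @param graph a `tf_graph`.
#' @param partition a `tf_partition` covering the graph.
#' @param hub_threshold broadcast label cut-off (default 0.5).
#' @return Object of class `tf_network_summary`: `n_nodes`, `n_edges`,
#'   `isolate_fraction`, `cluster_sizes` (descending), and `clusters`
#'   (tibble `cluster`, `size`, `hub_concentration`, `broadcast_like`).
#' @export
summarize_network <- function(graph, partition, hub_threshold = 0.5) {
  memb <- partition$membership[graph$nodes]
  stopifnot(!anyNA(memb))
  e <- graph$edges[graph$edges$source != graph$edges$target, ]
  touched <- unique(c(e$source, e$target))
  isolate_fraction <- 1 - length(intersect(graph$nodes, touched)) /
    max(1L, length(graph$nodes))
  sizes <- sort(table(memb), decreasing = TRUE)
  ci <- memb[match(e$source, graph$nodes)]
  cj <- memb[match(e$target, graph$nodes)]
  clusters <- lapply(sort(unique(as.integer(memb))), function(cl) {
    within <- which(ci == cl & cj == cl)
    hub <- if (length(within)) {
      indeg <- rowsum(as.numeric(e$weight[within]), e$target[within])
      max(indeg) / sum(e$weight[within])
    } else {
      NA_real_
    }
    tibble::tibble(cluster = cl, size = sum(memb == cl),
                   hub_concentration = hub,
                   broadcast_like = !is.na(hub) & hub > hub_threshold)
  })
  clusters <- do.call(rbind, clusters)
  structure(list(n_nodes = length(graph$nodes), n_edges = nrow(graph$edges),
                 isolate_fraction = isolate_fraction,
                 cluster_sizes = as.integer(sizes),
                 clusters = clusters),
            class = "tf_network_summary")
}

#' @export
print.tf_network_summary <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d edges, isolate fraction %.3f\n",
              x$n_nodes, x$n_edges, x$isolate_fraction))
  cat("Cluster sizes:", paste(utils::head(x$cluster_sizes, 10),
                              collapse = ", "),
      if (length(x$cluster_sizes) > 10) "...\n" else "\n")
  invisible(x)
}

#' Convert an interaction graph to igraph
#'
#' Typed parallel edges are preserved as edge attributes `type` and
#' `weight`; self-loop tweet counts become the vertex attribute
#' `self_loops`.
#'
#' @param graph a `tf_graph`.
#' @return An [igraph::graph] object (directed).
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = TRUE,
    vertices = data.frame(name = graph$nodes)
  )
  loops <- rep(0L, length(graph$nodes))
  loops[match(names(graph$self_loops), graph$nodes)] <-
    as.integer(graph$self_loops)
  igraph::set_vertex_attr(g, "self_loops", value = loops)
}

#' Export an interaction graph
#'
#' @param graph a `tf_graph`.
#' @param path output file path.
#' @param format `"graphml"` (via igraph) or `"tsv"` (edge list with
#'   columns source, target, type, weight).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else {
    utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Write a cluster partition as CSV
#'
#' @param partition a `tf_partition`.
#' @param path output CSV path (columns node, cluster).
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(
    data.frame(node = names(partition$membership),
               cluster = as.integer(partition$membership)),
    path, row.names = FALSE)
  invisible(path)
}
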