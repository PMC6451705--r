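fixture_corpus <- function() {
  rbind(
    mk_tweet("n1", "A", rt_of = "B"),                     # retweet edge A->B
    mk_tweet("n2", "C", reply_to = "A"),                  # reply edge C->A
    mk_tweet("n3", "A", mentions = c("B", "C")),          # two mention edges
    mk_tweet("n4", "D", text = "nobody here")             # self-loop at D
  )
}

test_that("graph construction produces the exact typed edge list", {
  g <- build_graph(fixture_corpus())
  expect_setequal(g$nodes, c("A", "B", "C", "D"))
  got <- g$edges[order(g$edges$source, g$edges$target, g$edges$type), ]
  want <- tibble::tibble(
    source = c("A", "A", "A", "C"),
    target = c("B", "B", "C", "A"),
    type = c("mention", "retweet", "mention", "reply"),
    weight = 1L
  )
  want <- want[order(want$source, want$target, want$type), ]
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
  expect_equal(as.integer(g$self_loops["D"]), 1L)
  expect_equal(sum(g$self_loops), 1L)
})

test_that("every tweet makes edges or exactly one self-loop", {
  for (s in 1:6) {
    corp <- random_corpus(25, seed = 300 + s)
    g <- build_graph(corp)
    interacting <- lengths(corp$mention_ids) > 0 | corp$is_retweet |
      corp$is_reply
    expect_equal(sum(g$self_loops), sum(!interacting))
    expect_true(all(c(g$edges$source, g$edges$target) %in% g$nodes))
    expect_true(all(g$edges$weight >= 1))
  }
})

test_that("parallel interactions accumulate weight; silent mentions become nodes", {
  tw <- rbind(
    mk_tweet("m1", "A", mentions = "Z"),
    mk_tweet("m2", "A", mentions = "Z")
  )
  g <- build_graph(tw)
  expect_true("Z" %in% g$nodes)
  expect_equal(g$edges$weight, 2L)
})

test_that("clustering splits two 4-cliques joined by a bridge", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  g <- graph_from_adjacency(A)
  part <- cluster_graph(g)
  memb <- unname(part$membership)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[1:4])), 1L)
  expect_equal(length(unique(memb[5:8])), 1L)
  expect_equal(part$q, best_partition_q(A), tolerance = 1e-12)
})

test_that("degenerate and tiny graphs cluster sensibly", {
  # isolates only: every node its own cluster, q = 0, degenerate
  iso <- tweet_tbl(sprintf("t%d", 1:5), LETTERS[1:5])
  p <- cluster_graph(build_graph(iso))
  expect_true(p$degenerate)
  expect_equal(p$q, 0)
  expect_equal(length(unique(p$membership)), 5L)
  # single triangle: one cluster
  A <- matrix(1, 3, 3); diag(A) <- 0
  p3 <- cluster_graph(graph_from_adjacency(A))
  expect_equal(length(unique(p3$membership)), 1L)
})

test_that("modularity matches hand values and the igraph oracle", {
  # two disjoint triangles split by component: Q = 0.5 by hand
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  g <- graph_from_adjacency(A)
  expect_equal(modularity_q(g, rep(1:2, each = 3)), 0.5)
  expect_equal(modularity_q(g, rep(1L, 6)), 0)
  part <- cluster_graph(g)
  expect_equal(part$q, 0.5)
  expect_gte(part$q, modularity_q(g, rep(1L, 6)))
  # random graphs against igraph::modularity
  set.seed(21)
  for (i in 1:10) {
    Ar <- random_gnp_adj(sample(4:10, 1), runif(1, 0.2, 0.7))
    if (sum(Ar) == 0) next
    gr <- graph_from_adjacency(Ar)
    part <- cluster_graph(gr)
    ig <- igraph::graph_from_adjacency_matrix(Ar, mode = "undirected")
    expect_equal(modularity_q(gr, part$membership),
                 igraph::modularity(ig, unname(part$membership)),
                 tolerance = 1e-12)
  }
})

test_that("greedy clustering never exceeds the exhaustive optimum", {
  set.seed(22)
  for (i in 1:25) {
    A <- random_gnp_adj(sample(3:7, 1), runif(1, 0.2, 0.8))
    if (sum(A) == 0) next
    g <- graph_from_adjacency(A)
    expect_lte(cluster_graph(g)$q, best_partition_q(A) + 1e-9)
  }
})

test_that("network summary captures hubs, isolates and conservation", {
  # star K1,5 with spokes pointing at the hub
  tw <- do.call(rbind, lapply(1:5, function(i) {
    mk_tweet(paste0("s", i), paste0("u", i), mentions = "hub")
  }))
  g <- build_graph(tw)
  part <- cluster_graph(g)
  s <- summarize_network(g, part)
  expect_equal(length(unique(part$membership)), 1L)
  expect_equal(s$clusters$hub_concentration, 1)
  expect_true(s$clusters$broadcast_like)
  # 10 isolates + a triangle
  iso <- tweet_tbl(sprintf("i%02d", 1:10), sprintf("I%02d", 1:10))
  tri <- rbind(mk_tweet("a1", "X", mentions = "Y"),
               mk_tweet("a2", "Y", mentions = "Z"),
               mk_tweet("a3", "Z", mentions = "X"))
  g2 <- build_graph(rbind(iso, tri))
  s2 <- summarize_network(g2, cluster_graph(g2))
  expect_equal(s2$isolate_fraction, 10 / 13, tolerance = 1e-12)
  expect_equal(sum(s2$cluster_sizes), s2$n_nodes)
})

test_that("graph exports parse back", {
  g <- build_graph(fixture_corpus())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, tsv, "tsv")
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(g$edges))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), length(g$nodes))
  expect_equal(igraph::gsize(ig), nrow(g$edges))
})
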