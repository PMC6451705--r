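# helper: minimal profile tibble with given totals and noise elsewhere
fake_profiles <- function(n, tweets = 500, users = 500, seed = 1) {
  set.seed(seed)
  pv <- profile_variables()
  out <- tibble::tibble(condition = sprintf("c%03d", seq_len(n)))
  for (v in names(pv)) out[[v]] <- runif(n, 1, 50)
  out$total_tweets <- rep_len(tweets, n)
  out$total_users <- rep_len(users, n)
  out
}

test_that("size filter applies strict less-than bounds on both totals", {
  p <- fake_profiles(4)
  p$total_tweets <- c(99, 500, 100, 5000)
  p$total_users <- c(200, 49, 50, 1000)
  kept <- suppressMessages(filter_communities(p))
  expect_setequal(kept$condition, c("c003", "c004"))
  expect_equal(attr(kept, "n_excluded"), 2L)
  expect_error(suppressMessages(
    filter_communities(p, min_tweets = 1e9)), "filter")
})

test_that("dropping totals removes exactly the two size columns, idempotently", {
  p <- fake_profiles(5)
  expect_equal(ncol(p), 25L)
  d <- drop_totals(p)
  expect_equal(ncol(d), 23L)
  expect_false(any(c("total_tweets", "total_users") %in% names(d)))
  expect_identical(drop_totals(d), d)
})

test_that("standardization gives mean 0, sample sd 1, and is idempotent", {
  p <- tibble::tibble(condition = c("a", "b", "c"),
                      v1 = c(1, 2, 3), v2 = c(5, 5, 5))
  expect_warning(s <- standardize_profiles(p), "zero-variance")
  expect_equal(s$v1, c(-1, 0, 1))
  expect_equal(s$v2, c(0, 0, 0))
  expect_error(standardize_profiles(p[1, ]), "2 rows")
  set.seed(2)
  q <- tibble::tibble(a = rnorm(20, 50, 9), b = runif(20))
  s1 <- standardize_profiles(q)
  expect_lt(max(abs(colMeans(as.matrix(s1)))), 1e-12)
  expect_equal(apply(as.matrix(s1), 2, sd), c(a = 1, b = 1))
  expect_equal(standardize_profiles(s1), s1)
})

test_that("pearson_r handles exact, inverse and orthogonal cases", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_warning(r <- pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r))
})

test_that("pairwise table covers engagement x other facets, sorted by |r|", {
  p <- fake_profiles(40, seed = 5)
  p$mean_unique_words <- p$pct_like  # plant a perfect pair
  tab <- pairwise_engagement_correlation(p)
  expect_equal(nrow(tab), 6 * 16)
  expect_equal(tab$engagement_variable[1], "pct_like")
  expect_equal(tab$other_variable[1], "mean_unique_words")
  expect_equal(tab$r[1], 1)
  expect_true(all(diff(abs(tab$r)) <= 1e-12))
  expect_true(all(abs(tab$r) <= 1))
})

test_that("independent columns stay under the Monte-Carlo null bound", {
  set.seed(11)
  n <- 1000
  p <- tibble::tibble(condition = sprintf("c%04d", 1:n))
  for (v in names(profile_variables())) p[[v]] <- rnorm(n)
  tab <- pairwise_engagement_correlation(p)
  expect_lt(max(abs(tab$r)), 0.1)
})

test_that("cca_first recovers a shared column exactly", {
  set.seed(3)
  X <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("a", "b", "c")))
  Y <- cbind(y1 = X[, "a"])
  fit <- cca_first(X, Y)
  expect_equal(fit$r, 1, tolerance = 1e-6)
  expect_equal(names(which.max(abs(fit$weights_x))), "a")
  expect_equal(cor(fit$variate_x, fit$variate_y), fit$r, tolerance = 1e-6)
})

test_that("cca_first hits a planted population canonical correlation", {
  set.seed(4)
  b <- factor_blocks(5000, 4, 3, 0.8)
  fit <- cca_first(b$X, b$Y)
  expect_lt(abs(fit$r - 0.8), 0.03)
})

test_that("eigen solver agrees with optimizer and cancor oracles on small blocks", {
  set.seed(5)
  for (i in 1:10) {
    X <- matrix(rnorm(40 * 3), 40)
    Y <- matrix(rnorm(40 * 2), 40)
    fit <- cca_first(X, Y)
    expect_lt(abs(fit$r - optimizer_cca_r(X, Y)), 1e-4)
    expect_equal(fit$r, stats::cancor(scale(X), scale(Y))$cor[1],
                 tolerance = 1e-6)
  }
})

test_that("canonical correlation is invariant to per-column affine maps", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), 50)
  Y <- matrix(rnorm(50 * 2), 50)
  r0 <- cca_first(X, Y)$r
  X2 <- sweep(sweep(X, 2, c(2, -5, 0.1), "*"), 2, c(10, 0, -3), "+")
  Y2 <- sweep(Y, 2, c(-1, 100), "*")
  expect_equal(cca_first(X2, Y2)$r, r0, tolerance = 1e-8)
})

test_that("canonical r dominates every cross-block pairwise correlation", {
  set.seed(7)
  for (i in 1:10) {
    X <- matrix(rnorm(45 * 3), 45)
    Y <- matrix(rnorm(45 * 3), 45)
    r <- cca_first(X, Y)$r
    expect_gte(r + 1e-10, max(abs(cor(X, Y))))
  }
})

test_that("rank-deficient blocks error naming columns unless ridged", {
  set.seed(8)
  X <- matrix(rnorm(30 * 2), 30)
  X <- cbind(X, X[, 1] + X[, 2])
  colnames(X) <- c("u", "v", "w")
  Y <- matrix(rnorm(30 * 2), 30)
  expect_error(cca_first(X, Y, ridge = 0), "rank-deficient")
  expect_s3_class(cca_first(X, Y, ridge = 1e-8), "tf_cca")
})

test_that("loadings equal the block correlation matrix times the weights", {
  set.seed(9)
  X <- matrix(rnorm(80 * 4), 80)
  Y <- matrix(rnorm(80 * 3), 80)
  fit <- cca_first(X, Y)
  expect_equal(unname(fit$loadings_x),
               unname(drop(cor(X) %*% fit$weights_x)), tolerance = 1e-8)
  expect_true(all(abs(c(fit$loadings_x, fit$loadings_y)) <= 1 + 1e-12))
  # single-column block: loading is +-1
  f1 <- cca_first(X, Y[, 1, drop = FALSE])
  expect_equal(abs(unname(f1$loadings_y)), 1, tolerance = 1e-9)
})

test_that("sign convention makes repeated fits identical", {
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40)
  Y <- matrix(rnorm(40 * 2), 40)
  f1 <- cca_first(X, Y)
  f2 <- cca_first(X, Y)
  expect_identical(f1$weights_x, f2$weights_x)
  expect_gt(f1$weights_x[which.max(abs(f1$weights_x))], 0)
  expect_gte(cor(f1$variate_x, f1$variate_y), 0)
})

test_that("observed r sits inside the permutation null for independent blocks", {
  set.seed(12)
  hits <- 0
  trials <- 20
  for (t in seq_len(trials)) {
    X <- matrix(rnorm(60 * 3), 60)
    Y <- matrix(rnorm(60 * 2), 60)
    res <- cca_permutation(X, Y, n_perm = 200)
    # observed r below the 99th percentile of the permutation null
    if (res$p_value > 0.01) hits <- hits + 1
  }
  expect_gte(hits, 0.95 * trials - 1)
})

test_that("bias adjustment zeroes undetected correlations and keeps strong ones", {
  set.seed(13)
  b0 <- factor_blocks(300, 4, 3, 0)
  r0 <- cca_permutation(b0$X, b0$Y, n_perm = 199)
  expect_false(r0$detected)
  expect_equal(r0$r_adjusted, 0)
  expect_gt(r0$p_value, 0.01)
  b8 <- factor_blocks(300, 4, 3, 0.8)
  r8 <- cca_permutation(b8$X, b8$Y, n_perm = 199)
  expect_true(r8$detected)
  expect_lt(abs(r8$r_adjusted - 0.8), 0.06)
  expect_lt(r8$p_value, 0.01)
})

test_that("quartile bands report ranges, counts and mean community size", {
  p <- tibble::tibble(condition = letters[1:8],
                      pct_like = seq(10, 80, by = 10),
                      total_users = rep(100, 8))
  qs <- quartile_engagement_summary(p, "pct_like")
  expect_equal(qs$n_communities, rep(2L, 4))
  expect_equal(qs$mean_total_users, rep(100, 4))
  expect_equal(qs$min[1], 10)
  expect_equal(qs$max[4], 80)
  # permutation invariance
  qs2 <- quartile_engagement_summary(p[sample(8), ], "pct_like")
  expect_equal(qs, qs2)
  expect_error(quartile_engagement_summary(p[1:3, ], "pct_like"),
               "at least 4")
})

test_that("rankings are deterministic with alphabetical tie-breaks", {
  p <- tibble::tibble(condition = c("b", "a", "c"),
                      total_tweets = c(10, 5, 1),
                      total_users = c(3, 3, 2))
  r <- rank_communities(p, "tweets", k = 1)
  expect_equal(r$top$condition, "b")
  expect_equal(r$bottom$condition, "c")
  ru <- rank_communities(p, "users", k = 1)
  expect_equal(ru$top$condition, "a")  # tie 3/3 -> alphabetical
  expect_error(rank_communities(p, "tweets", k = 2), "half")
  expect_equal(formals(rank_communities)$k, 20)
})
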