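test_that("engagement metrics follow their stated denominators", {
  tw <- rbind(
    mk_tweet("t1", "A", rtc = 0, lkc = 1),
    mk_tweet("t2", "A", rtc = 2, lkc = 0),
    mk_tweet("t3", "B", rtc = 5, lkc = 0, reply_to = "A"),
    mk_tweet("t4", "B", rtc = 0, lkc = 3, quote_of = "A")
  )
  m <- engagement_metrics(tw)
  expect_equal(m[["pct_retweet"]], 50)
  expect_equal(m[["mean_retweet_freq"]], 3.5)
  expect_equal(m[["pct_like"]], 50)
  expect_equal(m[["mean_like_freq"]], 1)
  expect_equal(m[["pct_reply"]], 25)
  expect_equal(m[["pct_quote"]], 25)
  # corpus mode counts collected retweets instead
  tw2 <- rbind(tw, mk_tweet("t5", "C", rt_of = "A"))
  expect_equal(engagement_metrics(tw2, "corpus")[["pct_retweet"]], 20)
  expect_error(engagement_metrics(tw[0, ]), "empty")
  expect_warning(
    engagement_metrics(mk_tweet("t1", "A", rtc = 0)),
    "no retweeted tweets"
  )
})

test_that("user activity splits creators and propagators, which may overlap", {
  tw <- rbind(
    mk_tweet("t1", "A"), mk_tweet("t2", "A"),
    mk_tweet("t3", "B", rt_of = "A"),
    mk_tweet("t4", "C"), mk_tweet("t5", "C", rt_of = "A")
  )
  ua <- user_activity(tw)
  expect_equal(nrow(ua), 3L)
  expect_equal(ua$n_new_tweets[ua$user_id == "C"], 1L)
  expect_equal(ua$n_retweets[ua$user_id == "C"], 1L)
  p <- suppressWarnings(profile_community(tw))
  expect_equal(p$pct_ncc, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(p$pct_cp, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(p$mean_ncc_new_tweets, 1.5)
  expect_equal(p$mean_cp_retweets, 1)
  # all-retweeters edge
  rt_only <- rbind(mk_tweet("t1", "A", rt_of = "X"),
                   mk_tweet("t2", "B", rt_of = "X"))
  p2 <- suppressWarnings(profile_community(rt_only))
  expect_equal(p2$pct_ncc, 0)
  expect_equal(p2$pct_cp, 100)
  # single original author
  p3 <- suppressWarnings(profile_community(mk_tweet("t1", "A")))
  expect_equal(p3$pct_ncc, 100)
  expect_equal(p3$mean_ncc_new_tweets, 1)
  expect_equal(p3$total_users, 1)
  expect_equal(p3$pct_retweet, 0)
})

test_that("followers come from the user's latest tweet", {
  tw <- rbind(
    mk_tweet("t1", "A", followers = 10,
             at = as.POSIXct("2018-04-01", tz = "UTC")),
    mk_tweet("t2", "A", followers = 99,
             at = as.POSIXct("2018-04-09", tz = "UTC"))
  )
  expect_equal(user_activity(tw)$followers, 99)
  expect_equal(user_activity(tw[2:1, ])$followers, 99)
})

test_that("IQR outlier fraction matches hand-computed type-7 quartiles", {
  # [1,2,3,4,5,100]: Q1 = 2.25, Q3 = 4.75, fence = 4.75 + 1.5*2.5 = 8.5
  expect_equal(iqr_outlier_fraction(c(1, 2, 3, 4, 5, 100)),
               100 / 6, tolerance = 1e-12)
  # literal mode: fence = 1.5 * 4.75 = 7.125
  expect_equal(iqr_outlier_fraction(c(1, 2, 3, 4, 5, 100), "literal"),
               100 / 6, tolerance = 1e-12)
  expect_equal(iqr_outlier_fraction(rep(7, 10)), 0)
  expect_equal(iqr_outlier_fraction(rep(7, 10), "literal"), 0)
  expect_error(iqr_outlier_fraction(numeric(0)), "empty")
  expect_warning(out <- iqr_outlier_fraction(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, 0)
})

test_that("IQR fraction is invariant to permutation and translation", {
  set.seed(1)
  for (i in 1:10) {
    v <- rpois(30, 3)
    base <- iqr_outlier_fraction(v)
    expect_equal(iqr_outlier_fraction(sample(v)), base)
    expect_equal(iqr_outlier_fraction(v + 17.3), base)
  }
})

test_that("content metrics average entity and token counts", {
  tw <- rbind(
    mk_tweet("t1", "A", text = "new study new hope",
             tags = c("a", "b")),
    mk_tweet("t2", "B", text = "hi")
  )
  m <- content_metrics(tw)
  expect_equal(m[["mean_hashtags"]], 1)
  expect_equal(m[["mean_length"]], 2.5)
  expect_equal(m[["mean_unique_words"]], 2)
  expect_equal(m[["mean_media"]], 0)
})

test_that("profiles match the independent naive recount on the fixture", {
  expect_profile_matches_naive(reference_corpus())
})

test_that("profiles match the naive recount on random small corpora", {
  for (s in 1:15) {
    corp <- random_corpus(sample(5:20, 1), seed = 100 + s)
    expect_profile_matches_naive(corp)
  }
})

test_that("profile bounds hold on random corpora", {
  pv <- profile_variables()
  pct_vars <- grep("^pct_", names(pv), value = TRUE)
  for (s in 1:8) {
    p <- profile_community(random_corpus(30, seed = 200 + s))
    for (v in pct_vars) {
      expect_gte(p[[v]], 0)
      expect_lte(p[[v]], 100)
    }
    for (v in grep("^mean_", names(pv), value = TRUE)) {
      expect_gte(p[[v]], 0)
    }
    expect_lte(p$mean_unique_words, p$mean_length)
    expect_lte(p$total_users, p$total_tweets)
  }
})

test_that("profiles are local to their corpus", {
  corp <- reference_corpus()
  base <- profile_community(corp, "gout")
  # same authors appearing in another community do not perturb this one
  again <- profile_community(corp, "gout")
  expect_identical(base, again)
})

test_that("profile CSV round-trips with the stable facet column order", {
  profs <- rbind(profile_community(reference_corpus(), "gout"),
                 profile_community(random_corpus(12, seed = 3), "lupus"))
  expect_identical(names(profs), c("condition", names(profile_variables())))
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, f)
  back <- read_profiles(f)
  expect_equal(as.data.frame(back), as.data.frame(profs), tolerance = 1e-12)
})
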