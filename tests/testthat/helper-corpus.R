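# Fixture builders and an independent naive recount oracle for profiles.

mk_tweet <- function(id, author, text = "", tags = character(),
                     mentions = character(), urls = 0, media = 0,
                     rtc = 0, lkc = 0, rt_of = "", reply_to = "",
                     quote_of = "", followers = 0,
                     at = as.POSIXct("2018-04-20 12:00:00", tz = "UTC")) {
  tweet_tbl(
    tweet_id = id, author_id = author, text = text,
    created_at = at,
    hashtags = list(tags), mention_ids = list(mentions),
    url_count = urls, media_count = media,
    retweet_count = rtc, like_count = lkc,
    is_retweet = nzchar(rt_of), source_author_id = rt_of,
    is_reply = nzchar(reply_to), reply_to_user_id = reply_to,
    is_quote = nzchar(quote_of), quoted_author_id = quote_of,
    followers_count = followers
  )
}

# Reference corpus: 12 tweets, 6 users, covering originals, retweets,
# replies, quotes, mentions, media/urls and follower variation.
reference_corpus <- function() {
  at <- function(d) as.POSIXct(paste0("2018-04-", d, " 10:00:00"),
                               tz = "UTC")
  do.call(rbind, list(
    mk_tweet("t01", "A", "new gout study out today", c("gout"),
             rtc = 4, lkc = 6, urls = 1, followers = 120, at = at(10)),
    mk_tweet("t02", "A", "pain flare again", c("gout", "pain"),
             rtc = 0, lkc = 0, followers = 150, at = at(12)),
    mk_tweet("t03", "B", "see this thread", c("gout"), mentions = "A",
             rtc = 2, lkc = 1, media = 1, followers = 3000, at = at(11)),
    mk_tweet("t04", "C", "", c("gout"), rt_of = "A", rtc = 4, lkc = 6,
             followers = 45, at = at(12)),
    mk_tweet("t05", "C", "what helps you cope", c("gout"),
             reply_to = "B", rtc = 0, lkc = 2, followers = 45,
             at = at(13)),
    mk_tweet("t06", "D", "diet tips diet myths", c("gout"),
             rtc = 9, lkc = 0, urls = 2, followers = 800, at = at(14)),
    mk_tweet("t07", "D", "", c("gout"), rt_of = "B", rtc = 2, lkc = 1,
             followers = 810, at = at(15)),
    mk_tweet("t08", "D", "", c("gout"), rt_of = "A", rtc = 4, lkc = 6,
             followers = 820, at = at(16)),
    mk_tweet("t09", "E", "agree completely", c("gout"), quote_of = "D",
             rtc = 0, lkc = 3, followers = 60, at = at(17)),
    mk_tweet("t10", "E", "new new new words", c("gout"), mentions = c("A", "D"),
             rtc = 1, lkc = 0, followers = 62, at = at(18)),
    mk_tweet("t11", "F", "", c("gout"), rt_of = "D", rtc = 9, lkc = 0,
             followers = 5, at = at(19)),
    mk_tweet("t12", "B", "longer update with five words", c("gout"),
             rtc = 0, lkc = 1, urls = 1, followers = 3100, at = at(20))
  ))
}

# Random small corpus generator for property tests.
random_corpus <- function(n, n_users = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  users <- LETTERS[seq_len(n_users)]
  rows <- lapply(seq_len(n), function(i) {
    author <- sample(users, 1)
    kind <- sample(c("orig", "rt", "reply", "quote"), 1,
                   prob = c(0.5, 0.25, 0.15, 0.1))
    nw <- sample(0:6, 1)
    text <- paste(sample(c("one", "two", "three", "four", "go"),
                         nw, replace = TRUE), collapse = " ")
    mk_tweet(sprintf("t%03d", i), author, text,
             tags = c("gout", sample(c("x", "y"), sample(0:2, 1))),
             mentions = sample(users, sample(0:2, 1)),
             urls = rpois(1, 0.5), media = rpois(1, 0.3),
             rtc = rpois(1, 1.5), lkc = rpois(1, 1),
             rt_of = if (kind == "rt") sample(users, 1) else "",
             reply_to = if (kind == "reply") sample(users, 1) else "",
             quote_of = if (kind == "quote") sample(users, 1) else "",
             followers = rpois(1, 200),
             at = as.POSIXct("2018-04-01", tz = "UTC") + i * 3600)
  })
  do.call(rbind, rows)
}

# Independent naive recount of every profile field, written with loops
# and explicit arithmetic; deliberately not sharing code with the
# package implementation.
naive_profile <- function(tweets, iqr_mode = "tukey") {
  n <- nrow(tweets)
  orig <- list()
  for (i in seq_len(n)) if (!tweets$is_retweet[i]) orig <- c(orig, i)
  orig <- unlist(orig)
  n_orig <- length(orig)
  n_rt_ge1 <- 0; n_lk_ge1 <- 0; rt_vals <- c()
  for (i in orig) {
    if (tweets$retweet_count[i] >= 1) {
      n_rt_ge1 <- n_rt_ge1 + 1
      rt_vals <- c(rt_vals, tweets$retweet_count[i])
    }
    if (tweets$like_count[i] >= 1) n_lk_ge1 <- n_lk_ge1 + 1
  }
  users <- unique(tweets$author_id)
  n_new <- setNames(numeric(length(users)), users)
  n_rt <- setNames(numeric(length(users)), users)
  fol <- setNames(numeric(length(users)), users)
  fol_t <- setNames(rep(-Inf, length(users)), users)
  for (i in seq_len(n)) {
    u <- tweets$author_id[i]
    if (tweets$is_retweet[i]) n_rt[u] <- n_rt[u] + 1 else {
      n_new[u] <- n_new[u] + 1
    }
    ti <- as.numeric(tweets$created_at[i])
    if (is.na(ti)) ti <- -Inf
    if (ti >= fol_t[u]) {
      fol_t[u] <- ti
      fol[u] <- tweets$followers_count[i]
    }
  }
  ncc <- users[n_new >= 1]
  cp <- users[n_rt >= 1]
  out_frac <- function(v) {
    if (length(v) < 4) return(0)
    qs <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- if (iqr_mode == "tukey") {
      qs[2] + 1.5 * (qs[2] - qs[1])
    } else {
      1.5 * qs[2]
    }
    100 * sum(v > fence) / length(v)
  }
  n_words <- c(); n_uniq <- c()
  for (i in seq_len(n)) {
    tk <- tokenize(tweets$text[i])[[1]]
    n_words <- c(n_words, length(tk))
    n_uniq <- c(n_uniq, length(unique(tk)))
  }
  c(pct_retweet = 100 * n_rt_ge1 / n_orig,
    mean_retweet_freq = if (length(rt_vals)) sum(rt_vals) / length(rt_vals) else 0,
    pct_like = 100 * n_lk_ge1 / n_orig,
    mean_like_freq = sum(tweets$like_count) / n,
    pct_reply = 100 * sum(tweets$is_reply) / n,
    pct_quote = 100 * sum(tweets$is_quote) / n,
    total_users = length(users),
    pct_ncc = 100 * length(ncc) / length(users),
    pct_cp = 100 * length(cp) / length(users),
    mean_ncc_new_tweets = if (length(ncc)) sum(n_new[ncc]) / length(ncc) else 0,
    mean_cp_retweets = if (length(cp)) sum(n_rt[cp]) / length(cp) else 0,
    pct_ncc_outlier_by_nt = out_frac(n_new[ncc]),
    pct_cp_outlier_by_rt = out_frac(n_rt[cp]),
    mean_ncc_followers = if (length(ncc)) sum(fol[ncc]) / length(ncc) else 0,
    mean_cp_followers = if (length(cp)) sum(fol[cp]) / length(cp) else 0,
    pct_ncc_outlier_by_followers = out_frac(fol[ncc]),
    pct_cp_outlier_by_followers = out_frac(fol[cp]),
    total_tweets = n,
    mean_hashtags = sum(lengths(tweets$hashtags)) / n,
    mean_mentions = sum(lengths(tweets$mention_ids)) / n,
    mean_urls = sum(tweets$url_count) / n,
    mean_media = sum(tweets$media_count) / n,
    mean_unique_words = sum(n_uniq) / n,
    mean_length = sum(n_words) / n)
}

expect_profile_matches_naive <- function(tweets) {
  got <- profile_community(tweets, "c")
  want <- naive_profile(tweets)
  for (v in names(want)) {
    expect_equal(got[[v]], unname(want[[v]]), tolerance = 1e-12,
                 info = paste("variable", v))
  }
}
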