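#' Profile variables and their facets
#'
#' The community model describes each condition community with three
#' facets: level of engagement (how users interact with content), user
#' characteristics (who creates and who propagates content, and how
#' unusual the most active or most followed users are), and content
#' characteristics (observable tweet metadata). The two size totals are
#' kept for filtering and reporting but excluded from facet analyses.
#'
#' @return Named character vector mapping variable name to facet
#'   (`"engagement"`, `"user"`, `"content"` or `"totals"`), in the stable
#'   column order used by [write_profiles()].
#' @export
profile_variables <- function() {
  c(pct_retweet = "engagement", mean_retweet_freq = "engagement",
    pct_like = "engagement", mean_like_freq = "engagement",
    pct_reply = "engagement", pct_quote = "engagement",
    total_users = "totals",
    pct_ncc = "user", pct_cp = "user",
    mean_ncc_new_tweets = "user", mean_cp_retweets = "user",
    pct_ncc_outlier_by_nt = "user", pct_cp_outlier_by_rt = "user",
    mean_ncc_followers = "user", mean_cp_followers = "user",
    pct_ncc_outlier_by_followers = "user",
    pct_cp_outlier_by_followers = "user",
    total_tweets = "totals",
    mean_hashtags = "content", mean_mentions = "content",
    mean_urls = "content", mean_media = "content",
    mean_unique_words = "content", mean_length = "content")
}

facet_columns <- function(facet) {
  v <- profile_variables()
  names(v)[v == facet]
}

#' Engagement metrics for one corpus
#'
#' Six variables describing how much interaction a community's tweets
#' attract. The retweet and like shares are computed over original
#' (non-retweet) tweets, because the counts carried by a collected
#' retweet describe its source tweet; `retweet_share_mode = "corpus"`
#' instead reports the share of corpus tweets that *are* retweets.
#' Following the model's definitions, the mean retweet frequency averages
#' over retweeted originals only, while the mean like frequency averages
#' over all tweets.
#'
#' @param tweets a non-empty tweet tibble.
#' @param retweet_share_mode `"originals"` (default) or `"corpus"`.
#' @return Named numeric vector: `pct_retweet`, `mean_retweet_freq`,
#'   `pct_like`, `mean_like_freq`, `pct_reply`, `pct_quote`.
#' @export
engagement_metrics <- function(tweets,
                               retweet_share_mode = c("originals", "corpus")) {
  retweet_share_mode <- match.arg(retweet_share_mode)
  n <- nrow(tweets)
  if (n == 0L) stop("empty corpus")
  orig <- !tweets$is_retweet
  rtc <- tweets$retweet_count[orig]
  lkc <- tweets$like_count[orig]
  if (!any(orig)) {
    warning("corpus contains no original tweets; retweet/like shares set to 0")
    pct_rt <- if (retweet_share_mode == "corpus") 100 else 0
    return(c(pct_retweet = pct_rt, mean_retweet_freq = 0, pct_like = 0,
             mean_like_freq = mean(tweets$like_count), pct_reply = 0,
             pct_quote = 0))
  }
  pct_retweet <- if (retweet_share_mode == "corpus") {
    100 * sum(tweets$is_retweet) / n
  } else {
    100 * mean(rtc >= 1L)
  }
  mean_rt_freq <- if (any(rtc >= 1L)) mean(rtc[rtc >= 1L]) else {
    warning("no retweeted tweets; mean_retweet_freq set to 0")
    0
  }
  c(pct_retweet = pct_retweet,
    mean_retweet_freq = mean_rt_freq,
    pct_like = 100 * mean(lkc >= 1L),
    mean_like_freq = mean(tweets$like_count),
    pct_reply = 100 * sum(tweets$is_reply) / n,
    pct_quote = 100 * sum(tweets$is_quote) / n)
}

#' Per-user activity summary
#'
#' One row per distinct author: number of new (non-retweet) tweets,
#' number of retweets, and a follower count. New content creators (NCC)
#' are users with at least one new tweet; content propagators (CP) are
#' users with at least one retweet; the two sets may overlap. Follower
#' counts vary across a user's tweets over a collection window, so the
#' value observed on the user's latest tweet is taken (ties and missing
#' timestamps fall back to file order).
#'
#' @param tweets a tweet tibble.
#' @return Tibble with columns `user_id`, `n_new_tweets`, `n_retweets`,
#'   `followers`.
#' @export
user_activity <- function(tweets) {
  if (nrow(tweets) == 0L) {
    return(tibble::tibble(user_id = character(), n_new_tweets = integer(),
                          n_retweets = integer(), followers = integer()))
  }
  f <- factor(tweets$author_id)
  n_new <- as.integer(rowsum(as.numeric(!tweets$is_retweet), f))
  n_rt <- as.integer(rowsum(as.numeric(tweets$is_retweet), f))
  # latest tweet per user: order by time (NA last) then position
  t_num <- as.numeric(tweets$created_at)
  t_num[is.na(t_num)] <- -Inf
  ord <- order(as.integer(f), t_num, seq_len(nrow(tweets)))
  last_idx <- ord[cumsum(tabulate(f))]
  tibble::tibble(user_id = levels(f), n_new_tweets = n_new,
                 n_retweets = n_rt,
                 followers = tweets$followers_count[last_idx])
}

#' Share of values flagged as high outliers by the IQR rule
#'
#' With `mode = "tukey"` a value is an outlier above the standard upper
#' Tukey fence, Q3 + 1.5 * IQR. With `mode = "literal"` the fence is
#' simply 1.5 * Q3, a stricter reading that flags more values whenever
#' the quartiles are tight; it is retained for sensitivity analysis.
#' Quartiles use linear interpolation (type 7), so results at small n
#' depend on that convention.
#'
#' @param values numeric vector.
#' @param mode `"tukey"` (default) or `"literal"`.
#' @return Percentage of values above the fence, in `[0, 100]`.
#' @export
iqr_outlier_fraction <- function(values, mode = c("tukey", "literal")) {
  mode <- match.arg(mode)
  if (length(values) == 0L) stop("empty input")
  if (length(values) < 4L) {
    warning("fewer than 4 values; outlier fraction set to 0")
    return(0)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- if (mode == "tukey") q[2] + 1.5 * (q[2] - q[1]) else 1.5 * q[2]
  100 * sum(values > fence) / length(values)
}

#' Content metrics for one corpus
#'
#' Per-tweet means of hashtag, mention, URL and media counts, plus the
#' mean number of tokens (`mean_length`) and distinct tokens
#' (`mean_unique_words`) under [tokenize()].
#'
#' @inheritParams engagement_metrics
#' @return Named numeric vector of the six content variables.
#' @export
content_metrics <- function(tweets) {
  n <- nrow(tweets)
  if (n == 0L) stop("empty corpus")
  toks <- tokenize(tweets$text)
  wl <- lengths(toks)
  w <- unlist(toks, use.names = FALSE)
  if (length(w)) {
    grp <- rep.int(seq_len(n), wl)
    wid <- match(w, w)  # token identity as integer
    dup <- duplicated(grp * (length(w) + 1) + wid)
    wu <- tabulate(grp[!dup], nbins = n)
  } else {
    wu <- integer(n)
  }
  c(mean_hashtags = mean(lengths(tweets$hashtags)),
    mean_mentions = mean(lengths(tweets$mention_ids)),
    mean_urls = mean(tweets$url_count),
    mean_media = mean(tweets$media_count),
    mean_unique_words = mean(wu),
    mean_length = mean(wl))
}

#' Profile one condition community
#'
#' Assembles the full multifacet variable vector for a corpus: totals,
#' the six engagement variables, ten user variables (NCC/CP shares,
#' activity and follower means, and IQR outlier shares of NCC new-tweet
#' counts, CP retweet counts and both groups' follower counts), and the
#' six content variables. Deterministic for fixed input.
#'
#' @param tweets a non-empty tweet tibble (one condition's corpus).
#' @param condition community name; defaults to `"community"`.
#' @param iqr_mode passed to [iqr_outlier_fraction()].
#' @param retweet_share_mode passed to [engagement_metrics()].
#' @return One-row tibble with `condition` plus the 24 numeric variables
#'   of [profile_variables()].
#' @export
profile_community <- function(tweets, condition = "community",
                              iqr_mode = c("tukey", "literal"),
                              retweet_share_mode = c("originals", "corpus")) {
  vals <- profile_vector(tweets, condition, match.arg(iqr_mode),
                         match.arg(retweet_share_mode))
  out <- tibble::as_tibble(as.list(vals))
  tibble::add_column(out, condition = condition, .before = 1)
}

profile_vector <- function(tweets, condition, iqr_mode,
                           retweet_share_mode) {
  if (nrow(tweets) == 0L) stop("empty corpus for condition ", condition)
  eng <- engagement_metrics(tweets, retweet_share_mode)
  ua <- user_activity(tweets)
  cont <- content_metrics(tweets)
  ncc <- ua$n_new_tweets >= 1L
  cp <- ua$n_retweets >= 1L
  mean0 <- function(x) if (length(x)) mean(x) else 0
  # below 4 users the fence is meaningless: report 0 without the per-call
  # warning that iqr_outlier_fraction() itself would raise
  iqr0 <- function(x) {
    if (length(x) < 4L) 0 else iqr_outlier_fraction(x, iqr_mode)
  }
  usr <- c(
    pct_ncc = 100 * sum(ncc) / nrow(ua),
    pct_cp = 100 * sum(cp) / nrow(ua),
    mean_ncc_new_tweets = mean0(ua$n_new_tweets[ncc]),
    mean_cp_retweets = mean0(ua$n_retweets[cp]),
    pct_ncc_outlier_by_nt = iqr0(ua$n_new_tweets[ncc]),
    pct_cp_outlier_by_rt = iqr0(ua$n_retweets[cp]),
    mean_ncc_followers = mean0(ua$followers[ncc]),
    mean_cp_followers = mean0(ua$followers[cp]),
    pct_ncc_outlier_by_followers = iqr0(ua$followers[ncc]),
    pct_cp_outlier_by_followers = iqr0(ua$followers[cp])
  )
  vals <- c(eng, total_users = nrow(ua), usr, total_tweets = nrow(tweets),
            cont)
  vals[names(profile_variables())]
}

#' Profile every corpus in a collection
#'
#' @param corpora a `condition_corpora` list from [assign_conditions()] or
#'   [simulate_dataset()], or any named list of tweet tibbles.
#' @inheritParams profile_community
#' @return Tibble of community profiles, one row per condition, in the
#'   stable column order of [profile_variables()].
#' @export
profile_corpora <- function(corpora, iqr_mode = "tukey",
                            retweet_share_mode = "originals") {
  stopifnot(length(corpora) > 0L, !is.null(names(corpora)))
  m <- vapply(names(corpora), function(cond) {
    profile_vector(corpora[[cond]], cond, iqr_mode, retweet_share_mode)
  }, numeric(length(profile_variables())))
  out <- tibble::as_tibble(as.data.frame(t(m)))
  tibble::add_column(out, condition = names(corpora), .before = 1)
}

#' Read and write profile matrices
#'
#' Profiles are stored as a CSV matrix: one row per condition, one column
#' per variable, in the stable order of [profile_variables()].
#'
#' @param profiles a profile tibble.
#' @param path CSV path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tibble::as_tibble(df)
}
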