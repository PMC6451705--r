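#' Simulation configuration
#'
#' Parameters of the synthetic tweet-stream generator. The defaults
#' emulate a month-long hashtag harvest across many health conditions:
#' 379 communities whose user counts are log-uniform between 10 and
#' 10,000 (about a quarter of communities then fall under the 100-tweet /
#' 50-user analysis filter, and the corpus totals land near 1.5 million
#' tweets from roughly half a million users).
#'
#' Cross-facet dependence is planted at the community level: each
#' condition carries a latent content score u and a latent engagement
#' score e with cor(u, e) = `rho`. Content links drive per-tweet
#' mention/URL/media Poisson means and token counts from u; engagement
#' links drive retweet/like counts (negative binomial, overdispersed as
#' heavy-tailed social counts are) and reply/quote probabilities from e.
#' Each link is `c(intercept, slope)` on the log or logit scale.
#'
#' `topology_mix` gives (broadcast, community_clusters, isolates)
#' fractions: the isolates entry is the share of users in every
#' community whose tweets never interact, and each community's
#' remaining users are wired either hub-and-spoke (broadcast) or in
#' planted dense blocks (community clusters), drawn with probabilities
#' proportional to the first two entries.
#'
#' @param n_conditions number of condition communities.
#' @param users_range log-uniform range of community user counts.
#' @param tweets_per_ncc mean new tweets per creator (shifted Poisson,
#'   minimum 1).
#' @param ncc_share,cp_share baseline probabilities that a user creates
#'   new content / propagates content (at latent engagement 0; a user
#'   doing neither is made a creator).
#' @param retweets_per_cp mean retweets per propagator (shifted Poisson).
#' @param rho planted cross-facet correlation in `[0, 1]`.
#' @param engagement_link,content_link,user_link link coefficient lists;
#'   see Details in the package vignette.
#' @param followers_lognormal `c(meanlog, sdlog)` of per-user follower
#'   counts.
#' @param topology_mix named fractions summing to at most 1.
#' @param vocab_size Zipf vocabulary size for tweet text.
#' @param tags_per_condition hashtags per condition in the generated map.
#' @param seed master seed; per-condition child seeds derive from it so
#'   any one community can be regenerated stably.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_conditions = 379,
                       users_range = c(10, 10000),
                       tweets_per_ncc = 2.1,
                       ncc_share = 0.65,
                       cp_share = 0.55,
                       retweets_per_cp = 1.5,
                       rho = 0,
                       engagement_link = list(
                         retweet = c(log(1.3), 0.45), retweet_size = 2,
                         like = c(log(1.6), 0.3), like_size = 1.5,
                         reply = c(-2.2, 0.35), quote = c(-2.5, 0.35)),
                       content_link = list(
                         mentions = c(log(1.2), 0.22),
                         urls = c(log(0.9), 0.22),
                         media = c(log(0.6), 0.22),
                         hashtags_extra = 0.8,
                         length = c(log(7), 0.15)),
                       user_link = c(ncc = 0.3, cp = 0.3),
                       followers_lognormal = c(meanlog = 5.3, sdlog = 1.4),
                       topology_mix = c(broadcast = 0.45,
                                        community_clusters = 0.40,
                                        isolates = 0.15),
                       vocab_size = 2000,
                       tags_per_condition = 2,
                       seed = 1L) {
  stopifnot(n_conditions >= 1, length(users_range) == 2,
            users_range[1] >= 1, users_range[2] >= users_range[1],
            tweets_per_ncc >= 1, retweets_per_cp >= 1,
            rho >= 0, rho <= 1,
            ncc_share > 0, ncc_share <= 1, cp_share >= 0, cp_share <= 1,
            length(topology_mix) == 3, all(topology_mix >= 0),
            sum(topology_mix) <= 1 + 1e-9,
            vocab_size >= 10, tags_per_condition >= 1)
  structure(list(
    n_conditions = as.integer(n_conditions), users_range = users_range,
    tweets_per_ncc = tweets_per_ncc, ncc_share = ncc_share,
    cp_share = cp_share, retweets_per_cp = retweets_per_cp, rho = rho,
    engagement_link = engagement_link, content_link = content_link,
    user_link = user_link, followers_lognormal = followers_lognormal,
    topology_mix = topology_mix, vocab_size = as.integer(vocab_size),
    tags_per_condition = as.integer(tags_per_condition),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic hashtag-to-condition map
#'
#' Conditions are named `cond_0001`, ... with `tags_per_condition`
#' unique pseudo-hashtags each.
#'
#' @param n_conditions number of conditions (at least 1).
#' @param tags_per_condition hashtags per condition.
#' @return A `condition_map`.
#' @export
simulate_condition_map <- function(n_conditions, tags_per_condition = 2) {
  if (n_conditions < 1) stop("n_conditions must be at least 1")
  conds <- sprintf("cond_%04d", seq_len(n_conditions))
  condition_map(stats::setNames(lapply(seq_len(n_conditions), function(i) {
    sprintf("cond%04d%s", i, letters[seq_len(tags_per_condition)])
  }), conds))
}

sim_vocab <- function(vocab_size) {
  list(words = sprintf("w%05d", seq_len(vocab_size)),
       prob = (1 / seq_len(vocab_size)) /
         sum(1 / seq_len(vocab_size)))  # Zipf rank-frequency
}

#' Simulate one condition community
#'
#' Draws users (creator/propagator roles, follower counts), their new
#' tweets with engagement counts and content entities linked to the
#' community's latent scores, and propagator retweets of sampled
#' originals that copy the source's text and entities. Interaction
#' targets follow the community's topology type; isolate users' tweets
#' never interact.
#'
#' @param config a [sim_config()].
#' @param condition condition name.
#' @param tags character vector of the condition's hashtags.
#' @param latent_u,latent_e latent content and engagement scores.
#' @param n_users community size.
#' @param topology `"broadcast"` or `"community_clusters"`.
#' @param seed child seed for this community.
#' @return List: `tweets` (a tweet tibble), `truth` (list with planted
#'   block membership and hub set).
#' @export
simulate_community <- function(config, condition, tags, latent_u, latent_e,
                               n_users, topology = "community_clusters",
                               seed = 1L) {
  if (n_users < 1) stop("community needs at least one user")
  set.seed(seed)
  u <- latent_u; e <- latent_e
  el <- config$engagement_link; cl <- config$content_link
  user_ids <- paste0(condition, "_u", seq_len(n_users))
  followers <- as.integer(round(rlnorm(n_users,
                                       config$followers_lognormal[[1]],
                                       config$followers_lognormal[[2]])))
  # fixed isolate count per community: a binomial share would act as a
  # shared random factor suppressing mentions and replies together,
  # coupling the content and engagement facets even at rho = 0
  iso_share <- config$topology_mix[["isolates"]]
  isolate <- rep(FALSE, n_users)
  iso_n <- round(iso_share * n_users)
  if (iso_n > 0) isolate[sample.int(n_users, iso_n)] <- TRUE
  p_ncc <- plogis(qlogis(config$ncc_share) + config$user_link[["ncc"]] * e)
  p_cp <- plogis(qlogis(config$cp_share) + config$user_link[["cp"]] * e)
  is_ncc <- runif(n_users) < p_ncc
  is_cp <- !isolate & (runif(n_users) < p_cp)
  is_ncc[!is_ncc & !is_cp] <- TRUE

  # wiring targets
  n_hubs <- max(1L, round(0.02 * n_users))
  hubs <- user_ids[order(-followers)[seq_len(n_hubs)]]
  blocks <- NULL
  if (topology == "community_clusters") {
    eligible <- which(!isolate)
    k <- max(2L, round(length(eligible) / 25))
    blocks <- stats::setNames(sample.int(k, length(eligible), replace = TRUE),
                              user_ids[eligible])
  }
  draw_targets <- function(authors) {
    # one interaction target per slot; authors indexes into users
    M <- length(authors)
    if (M == 0L) return(character(0))
    out <- character(M)
    if (topology == "broadcast") {
      hub_pick <- runif(M) < 0.8
      out[hub_pick] <- sample(hubs, sum(hub_pick), replace = TRUE)
      out[!hub_pick] <- sample(user_ids, sum(!hub_pick), replace = TRUE)
    } else {
      blk <- blocks[user_ids[authors]]
      inb <- runif(M) < 0.9 & !is.na(blk)
      for (b in unique(blk[inb])) {
        w <- which(inb & blk == b)
        mates <- names(blocks)[blocks == b]
        out[w] <- sample(mates, length(w), replace = TRUE)
      }
      out[!inb] <- sample(user_ids, sum(!inb), replace = TRUE)
    }
    out
  }

  # originals ---------------------------------------------------------
  ncc_idx <- which(is_ncc)
  n_new <- 1L + rpois(length(ncc_idx), config$tweets_per_ncc - 1)
  # isolates are single-tweet users: one opinion or news tweet that
  # draws no interaction
  n_new[isolate[ncc_idx]] <- 1L
  author_idx <- rep.int(ncc_idx, n_new)
  N <- length(author_idx)
  author_iso <- isolate[author_idx]
  rtc <- rnbinom(N, size = el$retweet_size, mu = exp(el$retweet[1] +
                                                     el$retweet[2] * e))
  lkc <- rnbinom(N, size = el$like_size, mu = exp(el$like[1] +
                                                  el$like[2] * e))
  is_reply <- !author_iso & runif(N) < plogis(el$reply[1] + el$reply[2] * e)
  is_quote <- !is_reply & runif(N) < plogis(el$quote[1] + el$quote[2] * e)
  mn <- rpois(N, exp(cl$mentions[1] + cl$mentions[2] * u))
  mn[author_iso] <- 0L
  urls <- rpois(N, exp(cl$urls[1] + cl$urls[2] * u))
  media <- rpois(N, exp(cl$media[1] + cl$media[2] * u))
  n_tags <- 1L + rpois(N, cl$hashtags_extra)
  len <- 1L + rpois(N, exp(cl$length[1] + cl$length[2] * u))

  voc <- sim_vocab(config$vocab_size)
  tok <- sample.int(config$vocab_size, sum(len), replace = TRUE,
                    prob = voc$prob)
  text <- vapply(split(voc$words[tok], rep.int(seq_len(N), len)),
                 paste, "", collapse = " ")
  names(text) <- NULL

  decoys <- sprintf("topic%03d", seq_len(200))
  tag_main <- sample(tags, N, replace = TRUE)
  extra <- n_tags - 1L
  extra_tags <- sample(decoys, sum(extra), replace = TRUE)
  hashtags <- split(c(tag_main, extra_tags),
                    c(seq_len(N), rep.int(seq_len(N), extra)))
  names(hashtags) <- NULL

  mention_ids <- rep(list(character(0)), N)
  m_slot <- rep.int(seq_len(N), mn)
  m_targets <- draw_targets(rep.int(author_idx, mn))
  if (length(m_targets)) {
    sp <- split(m_targets, m_slot)
    mention_ids[as.integer(names(sp))] <- sp
  }
  reply_to <- character(N)
  reply_to[is_reply] <- draw_targets(author_idx[is_reply])
  # a quote with no mention/reply makes no graph edge, so even isolate
  # authors may quote
  quoted <- character(N)
  quoted[is_quote] <- sample(user_ids, sum(is_quote), replace = TRUE)

  window <- as.POSIXct(c("2018-04-15 00:00:00", "2018-05-15 00:00:00"),
                       tz = "UTC")
  t_orig <- window[1] + round(runif(N, 0, as.numeric(diff(window),
                                                     units = "secs")))

  # retweets by propagators -------------------------------------------
  cp_idx <- which(is_cp)
  rt_n <- if (length(cp_idx)) {
    1L + rpois(length(cp_idx), config$retweets_per_cp - 1)
  } else {
    integer(0)
  }
  rt_author_idx <- rep.int(cp_idx, rt_n)
  sourceable <- which(!author_iso)  # isolates' tweets are not propagated
  R <- if (length(sourceable)) length(rt_author_idx) else 0L
  rt_author_idx <- rt_author_idx[seq_len(R)]
  src <- if (R) {
    w <- rep(1, length(sourceable))
    if (topology == "broadcast") {
      w[user_ids[author_idx[sourceable]] %in% hubs] <- 5
    }
    sourceable[sample.int(length(sourceable), R, replace = TRUE,
                          prob = w / sum(w))]
  } else {
    integer(0)
  }
  t_rt <- window[1] + round(runif(R, 0, as.numeric(diff(window),
                                                   units = "secs")))

  all_author <- c(author_idx, rt_author_idx)
  tweets <- tweet_tbl(
    tweet_id = paste0(condition, "_t", seq_len(N + R)),
    author_id = user_ids[all_author],
    created_at = c(t_orig, t_rt),
    text = c(text, text[src]),
    hashtags = c(hashtags, hashtags[src]),
    mention_ids = c(mention_ids, mention_ids[src]),
    url_count = c(urls, urls[src]),
    media_count = c(media, media[src]),
    retweet_count = c(rtc, rtc[src]),
    like_count = c(lkc, lkc[src]),
    is_retweet = c(rep(FALSE, N), rep(TRUE, R)),
    source_author_id = c(rep("", N), user_ids[author_idx[src]]),
    is_reply = c(is_reply, rep(FALSE, R)),
    reply_to_user_id = c(reply_to, rep("", R)),
    is_quote = c(is_quote, rep(FALSE, R)),
    quoted_author_id = c(quoted, rep("", R)),
    followers_count = followers[all_author]
  )
  list(tweets = tweets,
       truth = list(condition = condition, topology = topology,
                    n_users = n_users, latent_content = u,
                    latent_engagement = e, blocks = blocks,
                    hubs = if (topology == "broadcast") hubs else NULL))
}

#' Simulate a full multi-condition dataset
#'
#' Draws per-condition latent content and engagement scores with the
#' planted correlation `config$rho` (a shared scaled latent factor),
#' community sizes, topology types and child seeds, then generates every
#' community corpus. With `dir` given, writes `tweets.jsonl` (the corpus
#' in the [read_tweets()] dialect), `condition_map.csv` and
#' `truth.json`; output is byte-identical for identical configurations.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if needed).
#' @return List: `corpora` (named list of tweet tibbles, class
#'   `condition_corpora`), `map` (a `condition_map`), `truth` (planted
#'   parameters: `rho`, per-condition latents, topology, child seeds,
#'   block memberships), `paths` (when `dir` is given).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_conditions
  u <- rnorm(n)
  e <- config$rho * u + sqrt(1 - config$rho^2) * rnorm(n)
  n_users <- round(exp(runif(n, log(config$users_range[1]),
                             log(config$users_range[2]))))
  mix <- config$topology_mix
  p_bc <- if (mix[["broadcast"]] + mix[["community_clusters"]] > 0) {
    mix[["broadcast"]] / (mix[["broadcast"]] + mix[["community_clusters"]])
  } else {
    0
  }
  topo <- ifelse(runif(n) < p_bc, "broadcast", "community_clusters")
  child_seed <- sample.int(.Machine$integer.max - 1L, n)
  map <- simulate_condition_map(n, config$tags_per_condition)
  conds <- names(map)
  sims <- lapply(seq_len(n), function(i) {
    simulate_community(config, conds[i], map[[i]], u[i], e[i], n_users[i],
                       topo[i], child_seed[i])
  })
  corpora <- structure(stats::setNames(lapply(sims, `[[`, "tweets"), conds),
                       class = "condition_corpora",
                       n_dropped = 0L, n_assignments = NA_integer_)
  truth <- list(rho = config$rho, seed = config$seed,
                conditions = conds, latent_content = u,
                latent_engagement = e, n_users = n_users, topology = topo,
                child_seed = child_seed,
                blocks = lapply(sims, function(s) s$truth$blocks))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(tweets = file.path(dir, "tweets.jsonl"),
                  map = file.path(dir, "condition_map.csv"),
                  truth = file.path(dir, "truth.json"))
    all_tweets <- do.call(rbind, unname(lapply(sims, `[[`, "tweets")))
    write_tweets(all_tweets, paths$tweets)
    write_condition_map(map, paths$map)
    jsonlite::write_json(truth[c("rho", "seed", "conditions",
                                 "latent_content", "latent_engagement",
                                 "n_users", "topology", "child_seed")],
                         paths$truth, auto_unbox = FALSE, digits = NA)
  }
  list(corpora = corpora, map = map, truth = truth, paths = paths)
}
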