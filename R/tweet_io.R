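#' @keywords internal
tweet_columns <- function() {
  c("tweet_id", "author_id", "created_at", "text", "hashtags", "mention_ids",
    "url_count", "media_count", "retweet_count", "like_count",
    "is_retweet", "source_author_id", "is_reply", "reply_to_user_id",
    "is_quote", "quoted_author_id", "followers_count")
}

#' Construct a tweet table
#'
#' Builds the canonical tibble of tweet records used throughout the
#' package: one row per tweet, with list-columns for hashtag and mention
#' entities. Missing optional arguments get neutral defaults (zero counts,
#' empty entity lists, no linkage). Follower counts ride along with each
#' tweet because they are observed per status, not per user; see
#' [user_activity()] for how a single per-user value is derived.
#'
#' @param tweet_id,author_id character vectors (required, recycled to the
#'   longest input).
#' @param text tweet text.
#' @param created_at `POSIXct` (UTC) or `NA`.
#' @param hashtags,mention_ids list of character vectors (lowercase tags
#'   without `#`; user ids).
#' @param url_count,media_count,retweet_count,like_count non-negative
#'   integer vectors.
#' @param is_retweet,is_reply,is_quote logical flags.
#' @param source_author_id,reply_to_user_id,quoted_author_id linked user
#'   ids, `""` when the corresponding flag is `FALSE`.
#' @param followers_count follower count of the author at posting time.
#' @return A tibble with one row per tweet.
#' @export
tweet_tbl <- function(tweet_id, author_id, text = "",
                      created_at = .POSIXct(NA_real_, tz = "UTC"),
                      hashtags = list(character()),
                      mention_ids = list(character()),
                      url_count = 0L, media_count = 0L,
                      retweet_count = 0L, like_count = 0L,
                      is_retweet = FALSE, source_author_id = "",
                      is_reply = FALSE, reply_to_user_id = "",
                      is_quote = FALSE, quoted_author_id = "",
                      followers_count = 0L) {
  n <- max(length(tweet_id), length(author_id), length(text))
  if (!inherits(created_at, "POSIXct")) {
    created_at <- as.POSIXct(created_at, tz = "UTC")
  }
  out <- tibble::new_tibble(list(
    tweet_id = rep_len(as.character(tweet_id), n),
    author_id = rep_len(as.character(author_id), n),
    created_at = rep(created_at, length.out = n),
    text = rep_len(as.character(text), n),
    hashtags = rep_len(hashtags, n),
    mention_ids = rep_len(mention_ids, n),
    url_count = rep_len(as.integer(url_count), n),
    media_count = rep_len(as.integer(media_count), n),
    retweet_count = rep_len(as.integer(retweet_count), n),
    like_count = rep_len(as.integer(like_count), n),
    is_retweet = rep_len(as.logical(is_retweet), n),
    source_author_id = rep_len(as.character(source_author_id), n),
    is_reply = rep_len(as.logical(is_reply), n),
    reply_to_user_id = rep_len(as.character(reply_to_user_id), n),
    is_quote = rep_len(as.logical(is_quote), n),
    quoted_author_id = rep_len(as.character(quoted_author_id), n),
    followers_count = rep_len(as.integer(followers_count), n)
  ), nrow = n)
  validate_tweets(out)
  out
}

#' Validate a tweet table
#'
#' Checks the record invariants: unique tweet ids, non-negative counts,
#' and that every retweet/reply/quote flag is backed by a linked user id.
#'
#' @param tweets a tweet tibble.
#' @return `tweets`, invisibly; errors on the first violated invariant.
#' @export
validate_tweets <- function(tweets) {
  stopifnot(is.data.frame(tweets))
  missing_cols <- setdiff(tweet_columns(), names(tweets))
  if (length(missing_cols)) {
    stop("tweet table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tweets$tweet_id)) {
    stop("duplicate tweet_id in corpus: ",
         tweets$tweet_id[anyDuplicated(tweets$tweet_id)])
  }
  for (col in c("url_count", "media_count", "retweet_count", "like_count",
                "followers_count")) {
    if (any(tweets[[col]] < 0L, na.rm = TRUE)) {
      stop("negative values in ", col)
    }
  }
  if (any(tweets$is_retweet & !nzchar(tweets$source_author_id))) {
    stop("retweet without source_author_id")
  }
  if (any(tweets$is_reply & !nzchar(tweets$reply_to_user_id))) {
    stop("reply without reply_to_user_id")
  }
  if (any(tweets$is_quote & !nzchar(tweets$quoted_author_id))) {
    stop("quote without quoted_author_id")
  }
  invisible(tweets)
}

normalize_tag <- function(x) {
  tolower(sub("^#", "", trimws(as.character(x))))
}

parse_tweet_json <- function(obj) {
  if (is.null(obj$id) || is.null(obj$user$id) || is.null(obj$text)) {
    stop("missing required field (id, user.id or text)")
  }
  ents <- obj$entities
  tags <- vapply(ents$hashtags, function(h) normalize_tag(h$text), "")
  mentions <- vapply(ents$user_mentions, function(m) {
    as.character(if (!is.null(m$id)) m$id else m$id_str)
  }, "")
  rt <- obj$retweeted_status
  created <- NA_character_
  if (!is.null(obj$created_at)) created <- as.character(obj$created_at)
  quoted <- obj$quoted_status
  reply_to <- obj$in_reply_to_user_id
  rtc <- obj$retweet_count %||% 0L
  lkc <- obj$favorite_count %||% 0L
  if (rtc < 0 || lkc < 0) stop("negative count")
  list(
    tweet_id = as.character(obj$id),
    author_id = as.character(obj$user$id),
    created_at = created,
    text = as.character(obj$text),
    hashtags = tags,
    mention_ids = mentions,
    url_count = length(ents$urls),
    media_count = length(ents$media),
    retweet_count = as.integer(rtc),
    like_count = as.integer(lkc),
    is_retweet = !is.null(rt),
    source_author_id = if (!is.null(rt)) as.character(rt$user$id) else "",
    is_reply = !is.null(reply_to) && nzchar(reply_to),
    reply_to_user_id = if (!is.null(reply_to)) as.character(reply_to) else "",
    is_quote = !is.null(quoted),
    quoted_author_id = if (!is.null(quoted)) as.character(quoted$user$id) else "",
    followers_count = as.integer(obj$user$followers_count %||% 0L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tweet corpus from JSON Lines
#'
#' Parses a UTF-8 JSON Lines file in the classic Twitter API v1.1 dialect
#' (`id`, `user`, `entities` with `hashtags`/`user_mentions`/`urls`/`media`,
#' `retweet_count`, `favorite_count`, `retweeted_status`,
#' `in_reply_to_user_id`, `quoted_status`). Hashtags are lowercased with
#' the leading `#` stripped.
#'
#' @param path path to a `.jsonl` file, one JSON object per line.
#' @param strict if `TRUE`, any malformed line is an error naming the line
#'   number; otherwise malformed lines are skipped, counted, and reported
#'   with a message.
#' @return A tweet tibble (see [tweet_tbl()]) with attribute `n_skipped`.
#' @export
read_tweets <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch({
      parse_tweet_json(jsonlite::parse_json(lines[[i]]))
    }, error = function(e) {
      if (strict) {
        stop("parse error at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
      NULL
    })
    if (is.null(rec)) skipped <- skipped + 1L else records[[i]] <- rec
  }
  records <- records[!vapply(records, is.null, TRUE)]
  out <- if (length(records)) {
    fld <- function(name, fun) fun(records, function(r) r[[name]])
    chr <- function(name) fld(name, function(l, f) vapply(l, f, ""))
    int <- function(name) fld(name, function(l, f) vapply(l, f, 0L))
    lgl <- function(name) fld(name, function(l, f) vapply(l, f, TRUE))
    tweet_tbl(
      tweet_id = chr("tweet_id"), author_id = chr("author_id"),
      created_at = as.POSIXct(chr("created_at"), tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                             "%Y-%m-%d %H:%M:%S")),
      text = chr("text"),
      hashtags = lapply(records, `[[`, "hashtags"),
      mention_ids = lapply(records, `[[`, "mention_ids"),
      url_count = int("url_count"), media_count = int("media_count"),
      retweet_count = int("retweet_count"), like_count = int("like_count"),
      is_retweet = lgl("is_retweet"),
      source_author_id = chr("source_author_id"),
      is_reply = lgl("is_reply"), reply_to_user_id = chr("reply_to_user_id"),
      is_quote = lgl("is_quote"), quoted_author_id = chr("quoted_author_id"),
      followers_count = int("followers_count")
    )
  } else {
    tweet_tbl(character(), character())
  }
  validate_tweets(out)
  if (skipped > 0L) {
    message("read_tweets: skipped ", skipped, " malformed line(s)")
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Write a tweet corpus as JSON Lines
#'
#' Inverse of [read_tweets()]: `read_tweets(write_tweets(x))` reproduces
#' `x` field for field (URL and media entities are emitted as placeholder
#' objects, so only their counts round-trip).
#'
#' @param tweets a tweet tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  validate_tweets(tweets)
  n <- nrow(tweets)
  d <- as.list(tweets)
  ts <- format(d$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lines <- character(n)
  for (i in seq_len(n)) {
    obj <- list(
      id = d$tweet_id[i],
      user = list(id = d$author_id[i],
                  followers_count = d$followers_count[i]),
      text = d$text[i],
      entities = list(
        hashtags = lapply(d$hashtags[[i]], function(t) list(text = t)),
        user_mentions = lapply(d$mention_ids[[i]], function(m) list(id = m)),
        urls = rep(list(list(url = "")), d$url_count[i]),
        media = rep(list(list(type = "photo")), d$media_count[i])
      ),
      retweet_count = d$retweet_count[i],
      favorite_count = d$like_count[i]
    )
    if (!is.na(ts[i])) obj$created_at <- ts[i]
    if (d$is_retweet[i]) {
      obj$retweeted_status <- list(user = list(id = d$source_author_id[i]))
    }
    if (d$is_reply[i]) obj$in_reply_to_user_id <- d$reply_to_user_id[i]
    if (d$is_quote[i]) {
      obj$quoted_status <- list(user = list(id = d$quoted_author_id[i]))
    }
    lines[i] <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Build a hashtag-to-condition map
#'
#' @param entries named list: condition name -> character vector of
#'   hashtags. Tags are lowercased and stripped of `#`.
#' @return An object of class `condition_map` (a named list of unique
#'   lowercase tags per condition).
#' @export
condition_map <- function(entries) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  entries <- lapply(entries, function(tags) unique(normalize_tag(tags)))
  if (any(lengths(entries) == 0L)) {
    stop("condition with empty hashtag set: ",
         paste(names(entries)[lengths(entries) == 0L], collapse = ", "))
  }
  all_tags <- unlist(entries, use.names = FALSE)
  dup <- unique(all_tags[duplicated(all_tags)])
  if (length(dup)) {
    warning("hashtag(s) mapped to more than one condition: ",
            paste(dup, collapse = ", "),
            "; tweets carrying them count in every mapped condition")
  }
  structure(entries, class = "condition_map")
}

#' Read a hashtag-to-condition map from CSV
#'
#' Expects header columns `hashtag,condition`, mirroring curated disease
#' hashtag lists in which one condition may own several tags (for example
#' `#Diabetes` and `#Diabetic` both mapping to diabetes). Duplicate rows
#' collapse; a tag claimed by two conditions is kept in both with a
#' warning.
#'
#' @param path CSV file path.
#' @return A `condition_map`.
#' @export
read_condition_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("hashtag", "condition") %in% names(df))) {
    stop("condition map needs columns 'hashtag' and 'condition'")
  }
  df$hashtag <- normalize_tag(df$hashtag)
  df <- unique(df[, c("hashtag", "condition")])
  condition_map(split(df$hashtag, df$condition))
}

#' @rdname read_condition_map
#' @param map a `condition_map` to serialise.
#' @export
write_condition_map <- function(map, path) {
  df <- data.frame(
    hashtag = unlist(map, use.names = FALSE),
    condition = rep(names(map), lengths(map)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assign tweets to condition communities
#'
#' A tweet joins the corpus of every condition whose hashtag set
#' intersects the tweet's hashtags (case-insensitively), so a tweet tagged
#' for two diseases is counted in both communities. Tweets matching no
#' condition are dropped and counted.
#'
#' @param tweets a tweet tibble.
#' @param map a `condition_map`.
#' @return A named list of per-condition tweet tibbles (class
#'   `condition_corpora`), with attributes `n_dropped` and
#'   `n_assignments`.
#' @export
assign_conditions <- function(tweets, map) {
  stopifnot(inherits(map, "condition_map"))
  if (length(map) == 0L) stop("empty condition map")
  tag2cond <- data.frame(
    tag = unlist(map, use.names = FALSE),
    condition = rep(names(map), lengths(map)),
    stringsAsFactors = FALSE
  )
  tw_tag <- data.frame(
    row = rep.int(seq_len(nrow(tweets)), lengths(tweets$hashtags)),
    tag = unlist(tweets$hashtags, use.names = FALSE)
  )
  hits <- merge(tw_tag, tag2cond, by = "tag")
  hits <- unique(hits[, c("row", "condition")])
  matched_rows <- unique(hits$row)
  n_dropped <- nrow(tweets) - length(matched_rows)
  corpora <- lapply(split(hits$row, hits$condition),
                    function(rows) tweets[sort(rows), ])
  # stable order: condition name
  corpora <- corpora[order(names(corpora))]
  if (n_dropped > 0L) {
    message("assign_conditions: dropped ", n_dropped,
            " tweet(s) matching no condition")
  }
  structure(corpora, class = "condition_corpora",
            n_dropped = n_dropped, n_assignments = nrow(hits))
}

#' Tokenize tweet text
#'
#' Lowercases, removes URL substrings, splits on whitespace, strips
#' leading/trailing punctuation from each token and drops empty tokens.
#' This is the tokenisation behind the mean-words and mean-unique-words
#' profile variables.
#'
#' @param text character vector.
#' @return A list of character token vectors, one element per input
#'   string.
#' @export
tokenize <- function(text) {
  x <- tolower(as.character(text))
  has_url <- grepl("://", x, fixed = TRUE) | grepl("www.", x, fixed = TRUE)
  x[has_url] <- gsub("(https?://|www\\.)\\S+", " ", x[has_url], perl = TRUE)
  x <- trimws(x)
  toks <- strsplit(x, "[[:space:]]+", perl = TRUE)
  toks[!nzchar(x)] <- list(character(0))
  punct <- which(grepl("[[:punct:]]", x, perl = TRUE))
  toks[punct] <- lapply(toks[punct], function(t) {
    t <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", t, perl = TRUE)
    t[nzchar(t)]
  })
  toks
}
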