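#' Exclude extremely small communities
#'
#' Very small communities yield unreliable statistics, so conditions with
#' fewer than `min_tweets` tweets or fewer than `min_users` users are
#' removed before correlation analysis. Both bounds are strict
#' "less than" rules: a community at exactly (100 tweets, 50 users) is
#' retained under the defaults.
#'
#' @param profiles a profile tibble (totals present).
#' @param min_tweets,min_users retention thresholds (defaults 100 and 50).
#' @return The retained rows; attribute `n_excluded` records the rest.
#' @export
filter_communities <- function(profiles, min_tweets = 100, min_users = 50) {
  keep <- profiles$total_tweets >= min_tweets &
    profiles$total_users >= min_users
  if (!any(keep)) {
    stop("no community passes the size filter; lower min_tweets/min_users")
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message("filter_communities: excluded ", n_excluded,
            " small communit", if (n_excluded == 1L) "y" else "ies")
  }
  out <- profiles[keep, ]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Drop the size totals from an analysis matrix
#'
#' Communities are compared regardless of their sizes, so `total_tweets`
#' and `total_users` are removed from the analysis matrix (they remain
#' available upstream for filtering and reporting). Idempotent.
#'
#' @param profiles a profile tibble.
#' @return The tibble without totals columns.
#' @export
drop_totals <- function(profiles) {
  profiles[, setdiff(names(profiles), facet_columns("totals"))]
}

#' Standardize profile variables
#'
#' Centers each numeric column to mean 0 and scales to sample standard
#' deviation 1 (denominator n - 1), so variables on different scales
#' (percentages vs counts) are comparable. Zero-variance columns become
#' all-zero with a warning.
#'
#' @param profiles a profile tibble with at least 2 rows.
#' @return The standardized tibble.
#' @export
standardize_profiles <- function(profiles) {
  if (nrow(profiles) < 2L) stop("need at least 2 rows to standardize")
  num <- vapply(profiles, is.numeric, TRUE)
  for (col in names(profiles)[num]) {
    x <- profiles[[col]]
    s <- stats::sd(x)
    if (s < 1e-12) {
      warning("zero-variance column ", col, " standardized to all-zero")
      profiles[[col]] <- rep(0, length(x))
    } else {
      profiles[[col]] <- (x - mean(x)) / s
    }
  }
  profiles
}

#' Pearson correlation with a guarded degenerate case
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return The product-moment correlation, or `NA` with a warning when
#'   either input has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Pairwise correlations of engagement with the other facets
#'
#' Every one of the six engagement variables against every user and
#' content variable, sorted by absolute correlation descending.
#'
#' @param profiles a (typically filtered and standardized) profile
#'   tibble; Pearson correlation is scale-invariant, so standardization
#'   is not required.
#' @return Tibble with columns `engagement_variable`, `other_variable`,
#'   `other_facet`, `r`, `n`.
#' @export
pairwise_engagement_correlation <- function(profiles) {
  eng <- intersect(facet_columns("engagement"), names(profiles))
  other <- intersect(c(facet_columns("user"), facet_columns("content")),
                     names(profiles))
  fac <- profile_variables()
  grid <- expand.grid(engagement_variable = eng, other_variable = other,
                      stringsAsFactors = FALSE)
  r <- mapply(function(a, b) {
    suppressWarnings(pearson_r(profiles[[a]], profiles[[b]]))
  }, grid$engagement_variable, grid$other_variable)
  out <- tibble::tibble(
    engagement_variable = grid$engagement_variable,
    other_variable = grid$other_variable,
    other_facet = unname(fac[grid$other_variable]),
    r = unname(r),
    n = nrow(profiles)
  )
  out[order(-abs(out$r)), ]
}

#' Quartile bands of an engagement variable
#'
#' Splits communities into four bands at the type-7 quartiles of
#' `variable` and reports, per band, the value range, the number of
#' communities, and the mean community size in users -- the summary
#' behind "communities with high engagement by this measure tend to be
#' smaller".
#'
#' @param profiles a profile tibble with `total_users` retained.
#' @param variable the engagement variable to band on.
#' @return Tibble with `quartile` (1 = lowest values), `min`, `max`,
#'   `n_communities`, `mean_total_users`.
#' @export
quartile_engagement_summary <- function(profiles, variable) {
  stopifnot(variable %in% names(profiles),
            "total_users" %in% names(profiles))
  x <- profiles[[variable]]
  if (length(x) < 4L) stop("need at least 4 communities")
  br <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  br <- unique(br)
  band <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- lapply(sort(unique(band)), function(b) {
    idx <- band == b
    tibble::tibble(quartile = b, min = min(x[idx]), max = max(x[idx]),
                   n_communities = sum(idx),
                   mean_total_users = mean(profiles$total_users[idx]))
  })
  do.call(rbind, out)
}

#' Top and bottom communities by size
#'
#' @param profiles a profile tibble.
#' @param by `"tweets"` or `"users"`.
#' @param k how many communities at each end (default 20); must not
#'   exceed half the number of communities.
#' @return List with `top` and `bottom` tibbles (`condition`, `value`),
#'   each sorted with the extreme first; ties broken by condition name
#'   ascending.
#' @export
rank_communities <- function(profiles, by = c("tweets", "users"), k = 20) {
  by <- match.arg(by)
  col <- if (by == "tweets") "total_tweets" else "total_users"
  n <- nrow(profiles)
  if (k > n / 2) stop("k must be at most half the number of communities")
  v <- profiles[[col]]
  ord_top <- order(-v, profiles$condition)
  ord_bot <- order(v, profiles$condition)
  pick <- function(ord) {
    tibble::tibble(condition = profiles$condition[ord[seq_len(k)]],
                   value = v[ord[seq_len(k)]])
  }
  list(top = pick(ord_top), bottom = pick(ord_bot))
}
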