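#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis into one fully
#' specified, loggable parameter set. Either `tweets_path` +
#' `map_path` (files in the package's JSONL/CSV formats) or an
#' in-memory `corpora` list must be supplied.
#'
#' @param out_dir output directory for run artifacts.
#' @param tweets_path,map_path input files for [read_tweets()] and
#'   [read_condition_map()].
#' @param corpora alternatively, a named list of tweet tibbles.
#' @param min_tweets,min_users community size filter (defaults 100/50).
#' @param iqr_mode,retweet_share_mode profile options.
#' @param ridge CCA regularisation.
#' @param n_perm permutations for the CCA test.
#' @param seed RNG seed for the permutation test and any subsampling.
#' @param hub_threshold broadcast label cut-off for network summaries.
#' @param network_conditions how many of the largest retained
#'   communities get network analysis.
#' @param network_max_users communities larger than this are analysed on
#'   a seeded subsample of that many users (network stage only).
#' @param rank_k list length for community rankings.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       tweets_path = NULL, map_path = NULL, corpora = NULL,
                       min_tweets = 100, min_users = 50,
                       iqr_mode = "tukey",
                       retweet_share_mode = "originals",
                       ridge = 1e-8, n_perm = 999, seed = 1L,
                       hub_threshold = 0.5, network_conditions = 12L,
                       network_max_users = 3000L, rank_k = 20L) {
  if (is.null(corpora) && (is.null(tweets_path) || is.null(map_path))) {
    stop("provide either corpora or both tweets_path and map_path")
  }
  structure(list(
    out_dir = out_dir, tweets_path = tweets_path, map_path = map_path,
    corpora = corpora, min_tweets = min_tweets, min_users = min_users,
    iqr_mode = iqr_mode, retweet_share_mode = retweet_share_mode,
    ridge = ridge, n_perm = n_perm, seed = as.integer(seed),
    hub_threshold = hub_threshold,
    network_conditions = as.integer(network_conditions),
    network_max_users = as.integer(network_max_users),
    rank_k = as.integer(rank_k)
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full community analysis pipeline
#'
#' Corpus to artifacts: per-community profiles, size rankings, quartile
#' summaries of the four engagement share variables, pairwise
#' engagement correlations, content-vs-engagement and
#' user-vs-engagement canonical correlation reports, per-community
#' interaction network exports with cluster partitions and numeric
#' summaries, and a JSON run manifest (parameters, versions, seed) from
#' which every numeric artifact is regenerable.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`profiles`,
#'   `retained`, `rankings`, `quartiles`, `pairwise`, `cca_content`,
#'   `cca_user`, `networks`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  corpora <- stage("load", {
    if (!is.null(config$corpora)) {
      config$corpora
    } else {
      tweets <- read_tweets(config$tweets_path)
      map <- read_condition_map(config$map_path)
      assign_conditions(tweets, map)
    }
  })

  profiles <- stage("profile", {
    profile_corpora(corpora, iqr_mode = config$iqr_mode,
                    retweet_share_mode = config$retweet_share_mode)
  })
  write_profiles(profiles, file.path(config$out_dir, "profiles.csv"))

  retained <- stage("filter", {
    filter_communities(profiles, config$min_tweets, config$min_users)
  })

  rankings <- stage("rank", {
    k <- min(config$rank_k, floor(nrow(profiles) / 2))
    if (k >= 1) {
      by_t <- rank_communities(profiles, "tweets", k)
      by_u <- rank_communities(profiles, "users", k)
      rbind(
        cbind(ranking = "top_by_tweets", by_t$top),
        cbind(ranking = "bottom_by_tweets", by_t$bottom),
        cbind(ranking = "top_by_users", by_u$top),
        cbind(ranking = "bottom_by_users", by_u$bottom)
      )
    } else {
      NULL
    }
  })
  if (!is.null(rankings)) {
    utils::write.csv(rankings, file.path(config$out_dir, "rankings.csv"),
                     row.names = FALSE)
  }

  quartiles <- stage("quartiles", {
    vars <- c("pct_retweet", "pct_like", "pct_reply", "pct_quote")
    if (nrow(retained) >= 4) {
      do.call(rbind, lapply(vars, function(v) {
        cbind(variable = v, quartile_engagement_summary(retained, v))
      }))
    } else {
      NULL
    }
  })
  if (!is.null(quartiles)) {
    utils::write.csv(quartiles, file.path(config$out_dir, "quartiles.csv"),
                     row.names = FALSE)
  }

  pairwise <- stage("pairwise", {
    if (nrow(retained) >= 3) {
      suppressWarnings(pairwise_engagement_correlation(
        standardize_profiles(drop_totals(retained))))
    } else {
      message("run_pipeline: too few communities for pairwise correlation")
      NULL
    }
  })
  if (!is.null(pairwise)) {
    utils::write.csv(pairwise, file.path(config$out_dir, "pairwise.csv"),
                     row.names = FALSE)
  }

  cca_report <- function(res, path) {
    fit <- if (inherits(res, "tf_cca")) res else res$cca
    fac <- profile_variables()
    df <- data.frame(
      variable = c(names(fit$weights_x), names(fit$weights_y)),
      facet = unname(fac[c(names(fit$weights_x), names(fit$weights_y))]),
      weight = c(fit$weights_x, fit$weights_y),
      loading = c(fit$loadings_x, fit$loadings_y)
    )
    utils::write.csv(df, path, row.names = FALSE)
    df
  }
  n_perm_eff <- if (nrow(retained) >= 12) config$n_perm else 0
  run_cca <- function(facet_x) {
    # CCA needs more communities than variables in the larger block
    n_vars <- max(length(facet_columns(facet_x)),
                  length(facet_columns("engagement")))
    if (nrow(retained) <= n_vars) {
      message("run_pipeline: too few communities for ", facet_x,
              "-engagement CCA; skipped")
      return(NULL)
    }
    stage(paste0("cca_", facet_x), {
      facet_cca(retained, facet_x, "engagement", n_perm = n_perm_eff,
                ridge = config$ridge)
    })
  }
  cca_content <- run_cca("content")
  if (!is.null(cca_content)) {
    cca_report(cca_content, file.path(config$out_dir, "cca_content.csv"))
  }
  cca_user <- run_cca("user")
  if (!is.null(cca_user)) {
    cca_report(cca_user, file.path(config$out_dir, "cca_user.csv"))
  }
  get_r <- function(res, what) {
    if (is.null(res)) {
      NA_real_
    } else if (inherits(res, "tf_cca")) {
      if (what == "r") res$r else NA_real_
    } else {
      res[[what]]
    }
  }
  cca_summary <- data.frame(
    pair = c("content_engagement", "user_engagement"),
    r = c(get_r(cca_content, "r"), get_r(cca_user, "r")),
    r_adjusted = c(get_r(cca_content, "r_adjusted"),
                   get_r(cca_user, "r_adjusted")),
    p_value = c(get_r(cca_content, "p_value"), get_r(cca_user, "p_value")),
    n = nrow(retained)
  )
  utils::write.csv(cca_summary, file.path(config$out_dir, "cca_summary.csv"),
                   row.names = FALSE)

  networks <- stage("network", {
    picked <- utils::head(
      retained$condition[order(-retained$total_tweets, retained$condition)],
      config$network_conditions)
    net_dir <- file.path(config$out_dir, "networks")
    dir.create(net_dir, showWarnings = FALSE)
    rows <- lapply(picked, function(cond) {
      tw <- corpora[[cond]]
      users <- unique(tw$author_id)
      if (length(users) > config$network_max_users) {
        keep_users <- sample(users, config$network_max_users)
        tw <- tw[tw$author_id %in% keep_users, ]
      }
      g <- build_graph(tw)
      part <- cluster_graph(g)
      summ <- summarize_network(g, part, config$hub_threshold)
      base <- file.path(net_dir, cond)
      export_graph(g, paste0(base, "_edges.tsv"), "tsv")
      export_graph(g, paste0(base, ".graphml"), "graphml")
      write_partition(part, paste0(base, "_clusters.csv"))
      data.frame(condition = cond, n_nodes = summ$n_nodes,
                 n_edges = summ$n_edges, modularity = part$q,
                 n_clusters = length(summ$cluster_sizes),
                 largest_cluster = summ$cluster_sizes[1],
                 isolate_fraction = summ$isolate_fraction,
                 n_broadcast_like = sum(summ$clusters$broadcast_like))
    })
    do.call(rbind, rows)
  })
  if (!is.null(networks)) {
    utils::write.csv(networks,
                     file.path(config$out_dir, "network_summary.csv"),
                     row.names = FALSE)
  }

  manifest <- config[setdiff(names(config), "corpora")]
  manifest$n_conditions <- nrow(profiles)
  manifest$n_retained <- nrow(retained)
  manifest$r_version <- R.version.string
  manifest$package_version <- as.character(utils::packageVersion("tweetfacets"))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  invisible(list(profiles = profiles, retained = retained,
                 rankings = rankings, quartiles = quartiles,
                 pairwise = pairwise, cca_content = cca_content,
                 cca_user = cca_user, networks = networks))
}
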