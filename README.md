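# tweetfacets

Comparative profiling of hashtag-defined health-condition communities on
Twitter: who engages, who creates versus propagates content, what the
content looks like, how the facets relate, and what the interaction
networks look like.

## The problem and the model

Health-condition communities on Twitter (all tweets carrying a curated
disease hashtag over a collection window) differ enormously in size, and
size does not track disease burden. The actionable question for health
communication is what moves *engagement*. `tweetfacets` models each
community c with a multivariate profile in three facets:

- **Engagement** E_c = (%Retweet, mean retweet freq, %Like, mean like
  freq, %Reply, %Quote);
- **User** U_c = (%NCC, %CP, mean new tweets per NCC, mean retweets per
  CP, follower means, and IQR-outlier shares of activity and followers),
  where an NCC (new content creator) authored at least one non-retweet
  and a CP (content propagator) retweeted at least once — overlapping
  sets, not a partition;
- **Content** C_c = per-tweet means of hashtags, mentions, URLs, media,
  words, unique words;

plus totals (tweets, users) used for filtering, ranking and quartile
summaries only. High-outlier shares use the Tukey fence Q3 + 1.5·IQR
with type-7 quartiles (a `literal` 1.5·Q3 mode is kept for sensitivity).

Communities with fewer than 100 tweets or 50 users are excluded, the
rest standardized, then two analyses run:

1. **Pairwise**: Pearson r between each engagement variable and each
   user/content variable.
2. **Canonical**: first-pair canonical correlation between facet blocks
   X and Y — weights a, b maximising r = cor(Xa, Yb), solved from the
   symmetric eigenproblem Sxx^(−1/2) Sxy Syy^(−1/2) (ridge 1e−8 for
   near-collinear variables), reported with canonical weights and
   loadings. Because the sample canonical correlation is biased upward
   at moderate n, a permutation test (stratified by community-size
   deciles) supplies a p-value and a permutation-calibrated,
   bias-adjusted estimate (see the methods vignette).

Per-community **interaction networks** have an edge author→user for
every mention, retweet (to the source author) and reply (to the target
user); non-interacting tweets add a self-loop. Graphs are clustered by
Clauset–Newman–Moore greedy modularity maximisation (implemented
in-package, deterministic tie-breaks) and summarised numerically:
isolate fraction, cluster sizes, and per-cluster hub concentration,
which flags broadcast-like (hub-and-spoke) clusters.

Because platform data cannot be redistributed, a seeded **synthetic
tweet generator** (`simulate_dataset()`) emulates the study conditions —
hundreds of communities with log-uniform sizes, overdispersed
engagement counts, Zipf text, configurable interaction topology — and
plants a community-level cross-facet correlation `rho` whose recovery
validates the whole pipeline end to end.

## Worked example

```r
library(tweetfacets)

cfg <- sim_config(n_conditions = 120, users_range = c(20, 2000),
                  rho = 0.7, seed = 42)
sim <- simulate_dataset(cfg, dir = "sim_data")

rc <- run_config(out_dir = "run_out",
                 tweets_path = sim$paths$tweets,
                 map_path = sim$paths$map,
                 n_perm = 499, network_conditions = 6)
res <- run_pipeline(rc)

round(res$cca_content$r, 4)
round(res$cca_content$r_adjusted, 4)
res$cca_content$p_value
head(res$pairwise, 3)
res$networks[1:3, c("condition", "n_nodes", "modularity", "isolate_fraction")]
```

```
#> filter_communities: excluded 26 small communities
#> [1] 0.7131
#> [1] 0.6722
#> [1] 0.002
#> # A tibble: 3 x 5
#>   engagement_variable other_variable other_facet     r     n
#>   <chr>               <chr>          <chr>       <dbl> <int>
#> 1 pct_retweet         pct_cp         user        0.844    94
#> 2 pct_like            pct_cp         user        0.813    94
#> 3 mean_like_freq      pct_cp         user        0.808    94
#>   condition n_nodes modularity isolate_fraction
#> 1 cond_0093    1937      0.535           0.1193
#> 2 cond_0108    1938      0.397           0.1254
#> 3 cond_0011    1822      0.309           0.0939
```

Reading: 94 of 120 simulated communities pass the 100-tweet/50-user
filter. The first canonical correlation between the content and
engagement facets comes out near the planted dependence of 0.7 — the
raw r (0.713) is biased up at 94 communities, and the
permutation-calibrated estimate (0.672, p = 0.002) is the number to
quote. The strongest single pairwise correlations are engagement-user
pairs (%Retweet and %Like against %CP): communities where more users
propagate content are communities where more tweets get retweeted and
liked. The per-community networks have modularity 0.3-0.5 and roughly
one user in eight isolated, matching the generator's topology
settings (15% single-tweet isolates).

The same pipeline runs from a shell:

```sh
inst/exec/tweetfacets simulate --conditions 120 --seed 42 -o sim_data
inst/exec/tweetfacets run --tweets sim_data/tweets.jsonl \
    --map sim_data/condition_map.csv -o run_out
```

Artifacts written to `run_out/`: `profiles.csv` (community × variable
matrix in stable column order), `rankings.csv` (top/bottom-k by tweets
and users), `quartiles.csv` (per-quartile value ranges, community
counts and mean user counts for the four engagement shares),
`pairwise.csv`, `cca_content.csv` / `cca_user.csv` (variable, facet,
weight, loading) with `cca_summary.csv`, per-community GraphML/TSV
exports and cluster partitions under `networks/`,
`network_summary.csv`, and `run_manifest.json` (every parameter,
versions and seed — the full provenance of the run).

## Input formats

- **Tweets**: UTF-8 JSON Lines, one object per line, in the classic
  Twitter API v1.1 dialect: `id`, `user` (`id`, `followers_count`),
  `text`, `created_at` (ISO 8601 UTC), `entities`
  (`hashtags`/`user_mentions`/`urls`/`media`), `retweet_count`,
  `favorite_count`, `retweeted_status`, `in_reply_to_user_id`,
  `quoted_status`.
- **Condition map**: CSV with header `hashtag,condition`; hashtags are
  case-folded and may be shared between conditions (a tweet then counts
  in each).

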