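Package: tweetfacets
Title: Multifacet Profiling of Hashtag-Defined Health Communities on Twitter
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares information-sharing behaviour across hashtag-defined
    health-condition communities on Twitter. Reads tweet corpora in the
    classic Twitter API JSON Lines dialect, assigns tweets to condition
    communities through a hashtag-to-condition map, and computes a
    multifacet engagement/user/content profile for each community,
    including interquartile-range outlier shares. Facets are related by
    pairwise Pearson correlation and first-pair canonical correlation
    analysis with a permutation-calibrated small-sample bias adjustment.
    Per-community directed mention/retweet/reply interaction graphs are
    clustered by greedy modularity maximisation and summarised
    numerically. A seeded synthetic tweet-stream generator with planted
    cross-facet correlation and controllable interaction topology supports
    end-to-end validation without any platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
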