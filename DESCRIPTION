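Package: forumnet
Title: Commenter-Overlap Network Profiling of Online Forum Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Profiles commenters of topic-focused online discussion forums
    (e.g. mental-health-related subreddits) from public comment archives.
    Groups forums into subtypes via weighted commenter-overlap networks and
    walktrap community detection combined with a recovery-term thread
    prevalence statistic, then profiles each subtype's commenters by the
    ancillary forums they also contribute to, using dual-rank selection,
    restricted overlap networks, and exhaustive Venn-style overlap
    accounting. Includes a seeded synthetic archive generator with planted
    community structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
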