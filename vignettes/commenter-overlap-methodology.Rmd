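---
title: "Profiling forum commenters with overlap networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling forum commenters with overlap networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumnet)
```

## The problem

Mental-health-related discussion forums (the motivating example is eating
disorder–related subreddits) are not interchangeable: some communities
encourage recovery while others normalise disordered behaviour, and the
people who comment on them have identifiable wider interests. `forumnet`
implements a two-stage, largely data-driven methodology for public
comment archives:

1. **Subtype discovery.** Group topically related forums into subtypes by
   *who comments where*: build a weighted network whose edge weights are
   commenter overlap, detect communities, and corroborate the grouping
   with a recovery-term text-mining statistic.
2. **Commenter profiling.** For each subtype, find the *ancillary* forums
   its commenters also contribute to, select the most representative
   fifty by a dual ranking, and repeat the network analysis restricted to
   the subtype's commenters to reveal their shared interests.

Everything operates on behavioural data (who commented in which forum and
thread), plus comment text for the single keyword statistic. No content
classification is attempted; qualitative labelling of forums and detected
communities is deliberately left to the analyst through editable label
files.

## The overlap statistic

For forums $A$ and $B$ with commenter sets of sizes $|A|$ and $|B|$
sharing $|A \cap B|$ commenters, the edge weight is the size-adjusted
mean of the two directed proportions:

$$ w(A,B) \;=\; \frac{1}{2}\left(\frac{|A\cap B|}{|A|} +
\frac{|A\cap B|}{|B|}\right) \in [0,1]. $$

Averaging the two directions stops large forums from swamping small ones:
a forum of 100 commenters sharing 40 with a forum of 50 gives
$(0.4 + 0.8)/2 = 0.6$. A forum's self-overlap is not meaningful as an
edge, so the matrix diagonal is fixed at zero. The full weighted matrix —
not a pruned version — is passed to community detection; an exclusive
`min_weight` threshold exists in `matrix_to_graph()` for sensitivity
analysis and display, and defaults to 0.

`pairwise_mean_overlap()` equals the Jaccard index only in degenerate
cases (disjoint sets, or identical equal-sized sets); in general it is
larger, because each proportion is normalised by one set rather than the
union.

## Community detection

`walktrap_dendrogram()` implements the random-walk agglomerative method
commonly used for networks of fewer than a thousand nodes, generalised to
weighted graphs:

* each vertex receives a self-loop weighted by the mean of its incident
  edge weights — the aperiodicity device used by the algorithm's
  reference implementation, adopted here so the two produce comparable
  merge sequences;
* transition probabilities are $P_{ij} = w_{ij}/s_i$ with $s_i$ the
  weighted degree (self-loop included);
* the distance between vertices (and, by member-averaging, communities)
  is the Euclidean distance between $t$-step walk distributions with each
  coordinate normalised by the destination's weighted degree;
* starting from singletons, only adjacent communities may merge, and each
  step performs the merge minimising the Ward-style increase in mean
  squared walk distance; exact ties are broken by the lexicographically
  smallest community-id pair so runs are reproducible across platforms.

The walk length defaults to $t = 4$, the customary choice for this
algorithm; it is exposed as `walk_length` in the pipeline configuration.
The final partition (`best_partition()`) is the dendrogram cut with
maximum weighted modularity

$$ Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} - \frac{s_i s_j}{2m}\right)
\delta(c_i, c_j), $$

with ties resolved toward fewer communities. Disconnected graphs are
handled per connected component with merge lists concatenated; the
component count is recorded in the dendrogram object.

Validation is dual-route: modularity is checked against a brute-force
double sum, cut selection against exhaustive modularity maximisation over
all 4,140 partitions of 8-node fixtures, and whole partitions against the
independent igraph implementation on random planted-block graphs. On
dense graphs with *no* community structure the two implementations can
occasionally return different partitions: merge decisions there hinge on
near-degenerate distance comparisons, and the reference stores distances
in single precision while this implementation works in doubles. The
agreement suite therefore samples random graphs with planted structure —
the regime the method is designed for — where agreement was observed on
200 of 200 seeds.

## Recovery focus

`recovery_focus()` reports, per forum, the percentage of comment threads
containing at least one of five terms: *recovery, recover, recovers,
recovered, recovering*. Because the list enumerates inflections
explicitly, matching is whole-word (tokens delimited by non-alphanumeric
characters) and case-insensitive: a substring rule would let "recover"
subsume the other four and also match "irrecoverable". Only comment text
is searched — public comment archives do not carry the thread's initial
post. A forum with zero threads has no defined percentage and raises an
error rather than returning a placeholder.

All reported percentages in the package go through one routine
(`pct()`), which rounds half-up to two decimals; base R's half-to-even
rounding would disagree with conventionally reported values on exact
halves.

## Ancillary profiling

The subtype's commenter set is the exact union over its member forums.
Ancillary candidates are all non-member forums reached by at least
`ancillary_inclusion_threshold(n)` subtype commenters — the smallest
integer count reaching 1%, i.e. $\lceil 0.01\,n\rceil$ (82 of 8,166; 16
of 1,580). Candidates are ranked twice, descending: by the number of
subtype commenters they attract, and by the proportion of their own
commenters belonging to the subtype. The selection key is the mean of
the two ranks, and the **top fifty are those with the numerically
smallest mean rank**: the selection's stated purpose is forums both large
in subtype-commenter count and high in subtype share, which is what small
rank numbers encode (rank 1 = largest). Fractional (average) ranking is
used for ties, keeping the mean-rank scale stable; residual ties in the
final ordering are broken alphabetically. Each ancillary forum's total
commenter count is taken after the global date-window and account
exclusions, the same universe every other statistic uses.

The restricted overlap network intersects every selected forum's
commenter set with the subtype's commenters before applying the same
overlap statistic, so the detected communities describe the subtype's
people, not the ancillary forums' general populations.

## Overlap accounting

`venn_partition()` classifies every commenter in the union of the
community sets by the exact subset of communities they posted in — all
$2^k - 1$ regions, counted exhaustively. The region table is the
normative output (the diagrams the counts feed are unscaled), so nothing
is lost for $k > 6$ where a diagram would be unreadable.
`group_exclusive_counts()` collapses the regions into only-group-A /
only-group-B / both; `community_participation()` and `coverage()` report
non-exclusive membership and reach percentages. Accounts whose name
contains "bot" are counted and summarised by `bot_name_report()` but
never filtered: heuristic bot removal also removes real users, so the
conservative choice is to report prevalence and let readers judge.

## The synthetic archive

`generator_config()` / `generate_archive()` produce a JSON-lines archive
in the public comment-dump schema with planted ground truth. Defaults
describe the validation conditions used throughout the test suite: 3
forum communities of 5 forums each, 3,000 commenters with a uniformly
random home community, cross-community contribution probability
$\varepsilon = 0.05$, heavy-tailed activity (discrete power law
$P(k) \propto k^{-2}$, $k \le 100$, minimum one comment — commenting on
public forums is strongly skewed, and single-comment accounts must
exist), 40 threads per forum, a 10% recovery-term thread rate, 0.7%
bot-named accounts, and the placeholder records (`AutoModerator`,
`[deleted]`) the ingest exclusions must handle. Timestamps are uniform
over a March 2017 – February 2018 window. The same configuration and
seed yield a byte-identical archive.

What the generator does **not** emulate: realistic text beyond the
injected keyword sentences (one non-recovery sentence deliberately
contains "irrecoverable" to exercise the whole-word rule end to end),
temporal bursts, thread reply structure, overlapping home communities, or
coordinated bot behaviour. Passing the planted-recovery benchmark
(median adjusted Rand index $\ge 0.9$ over 10 seeds; in practice 1.0 at
the default strength) therefore shows the pipeline's machinery is
correct, not that real forum communities are as cleanly separable.

## Degenerate inputs and numerical choices

* Empty commenter sets make the overlap undefined and raise errors
  naming the forum.
* Malformed or field-incomplete archive lines are counted and skipped
  with a warning — multi-gigabyte dumps should not abort on one bad
  line; unreadable files are fatal.
* Forum-name matching (discovery, exclusion lists) is case-insensitive
  because display names vary in case; commenter names are compared
  exactly because usernames are case-sensitive identities.
* Search-term matching is a case-insensitive substring over name plus
  short description; the discovery step always feeds a manual exclusion
  list, so recall is preferred over precision.
* Date windows are calendar months in UTC, both ends inclusive.
* Modularity of an edgeless graph is reported as 0.

## Validation scale

The test suite runs entirely on programmatically generated data: archive
fixtures of a few thousand records, networks of 8–20 nodes where
exhaustive oracles are feasible, and ten end-to-end runs at the default
generator conditions (15 forums, 3,000 commenters). These sizes were
chosen so every oracle (exhaustive partition enumeration, brute-force set
algebra) stays exact; the pipeline itself scales to archives limited only
by memory for the per-forum commenter sets.

## Known limitations

* One person with several accounts is several commenters
  (underestimating overlap); unflagged bots are commenters
  (overestimating it). Both are properties of the data, mitigated by
  interpreting communities rather than single forums.
* Readers who never comment are invisible to the method.
* The recovery statistic is a keyword prevalence, not a stance
  classifier; it corroborates network structure rather than measuring
  attitude.
* Walktrap's dendrogram constrains the modularity search; on graphs with
  weak structure the selected cut can fall below the global modularity
  optimum (the suite verifies it never exceeds it).
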