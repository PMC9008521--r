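---
title: "Measuring a decade of topical discourse: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring a decade of topical discourse: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discourselens)
library(data.table)
```

## The problem

Public conversation about a stigmatized topic — mental health is the
motivating case — changes slowly, over years, and in ways that single
surveys cannot resolve. A high-volume timestamped message stream (for
example a fixed-rate random sample of public posts) lets us ask four
quantitative questions:

1. How much is the topic talked about, day by day, relative to everything
   else? (rank time series of an *anchor phrase*)
2. What is the emotional tone of the conversation, and which words drive
   its changes? (ambient happiness and word shifts)
3. How does the topical vocabulary differ from the platform background?
   (rank-turbulence divergence)
4. Is the conversation driven by original posts or by sharing?
   (organic/retweet balance and amplification)

`discourselens` implements this pipeline end to end. Because the message
feeds such studies rely on are proprietary, the package also ships a
seeded synthetic stream generator that plants all of the phenomena the
pipeline is meant to detect, so every stage is testable from a cold start.

## Corpus construction

Messages are tokenized by splitting on Unicode whitespace and stripping
leading/trailing punctuation (a leading `#` or `@` survives, so hashtags
and handles are types). Case is folded to lowercase by default, which
maximizes matches against sentiment lexicons; it can be disabled. These
conventions are explicit configuration, not a claim about any upstream
dataset: corpora differ, and the tests pin the conventions rather than the
data.

For each UTC calendar day and each order $n \in \{1,2,3\}$ the ledger
records, per n-gram, a total count split into *organic* occurrences (from
original messages) and *retweeted* occurrences, with
`count_total = count_organic + count_retweet` as a hard invariant. The
anchored sub-corpus is the set of messages whose token sequence contains
the anchor phrase as adjacent tokens; matching happens on tokens, so
punctuation variants of the phrase match.

Ranking is by descending count with fractional (average) ranks for ties:
rank 1 is the most frequent type and the ranks of $N$ types always sum to
$N(N+1)/2$, which makes rank computations property-testable and keeps the
divergence module's conventions consistent. A day on which a target
n-gram is absent yields a missing rank, never a sentinel value.

## Ambient happiness and word shifts

Given a lexicon $h(w) \in [1, 9]$ (1 = saddest, 9 = happiest), the
ambient happiness of a corpus is the count-weighted mean over
lexicon-matched words:

$$h_{\text{avg}} = \frac{\sum_w h(w)\, c(w)}{\sum_w c(w)}.$$

Two conventions are deliberately configurable because the literature is
not uniform:

* **Lens.** An optional exclusion interval $(l, u)$ drops near-neutral
  words ($l < h(w) < u$) before scoring. The default is *off* — the
  plain mean over all matched words — with the conventional $(4, 6)$
  lens available by argument.
* **Anchor constituents.** The anchor's own words are *included* in
  ambient scoring by default (the literal reading of "average over all
  words in matching messages"); an `exclude` argument removes them.

Daily series are smoothed with a trailing 7-day mean that skips missing
days; a window with fewer than half its days available is itself missing.
Trailing (rather than centered) windows keep the smoothed value causal.

The difference between a comparison corpus and a reference corpus
decomposes exactly into per-word contributions

$$\delta h_w = \big(h(w) - h_{\text{ref}}\big)\,
              \big(p_{\text{comp}}(w) - p_{\text{ref}}(w)\big),
  \qquad \sum_w \delta h_w = h_{\text{comp}} - h_{\text{ref}},$$

where $p$ are frequencies over lexicon-matched tokens within each corpus.
Words present in only one corpus get $p = 0$ in the other; no smoothing
is applied because the formula is well-defined at zero. Each word is
classified by its valence relative to $h_{\text{ref}}$ and the direction
of its usage change (`pos_up`, `pos_down`, `neg_up`, `neg_down`), the
four classes that word-shift graphs color. The conservation identity is
the module's primary acceptance property and is tested to $10^{-9}$ on
hundreds of random corpus pairs.

The default reference for an event day is the *pooled* seven days
strictly before the event. "The prior week" is ambiguous between pooling
and the same weekday one week earlier, so both modes are explicit
(`pooled_week`, `same_day_prior_week`); pooling is the default because it
stabilizes reference frequencies for sparse anchored corpora. Ties in
$|\delta h_w|$ at the display cutoff are broken alphabetically so exports
are deterministic.

## Rank-turbulence divergence

Two ranked vocabularies $\Omega_1, \Omega_2$ are compared with

$$D_\alpha(\Omega_1 \,\|\, \Omega_2) \;=\; \frac{1}{\mathcal{N}}
  \frac{\alpha + 1}{\alpha} \sum_{\tau}
  \Big|\, r_{1}(\tau)^{-\alpha} - r_{2}(\tau)^{-\alpha} \Big|^{1/(\alpha+1)},$$

summing over the union of types. A type absent from system 2 receives
there the tied rank $N_2 + (N_{x1} + 1)/2$ — $N_2$ observed types, all
$N_{x1}$ system-1-exclusive types tied just past them — and symmetrically
for system 1. The normalization $\mathcal{N}$ is the same sum evaluated
in the all-disjoint hypothetical (each system keeps its observed ranks,
every type treated as exclusive), so $D = 1$ exactly for disjoint systems
and $D = 0$ iff the tied rankings coincide over identical support. The
exponent defaults to $\alpha = 1/3$, the convention in allotaxonometric
comparisons of heavy-tailed vocabularies; it is configurable on
$(0, \infty)$, and the $\alpha \to 0$ and $\alpha \to \infty$ limits are
excluded because they need special-case formulas that this package does
not implement. Near the ends of the range the statistic becomes
insensitive (small $\alpha$) or dominated by top ranks (large $\alpha$).

For 3-gram comparisons of an anchored corpus, every 3-gram whose first
two or last two tokens are the anchor itself can be removed
(`filter_anchor_phrases`) — such phrases are present by construction and
swamp the contribution table. Survivors are re-ranked.

The histogram export bins the completed rank pairs on a square grid in
$(\log_{10} r_1, \log_{10} r_2)$ with exclusive types in separate bands,
which is the unrotated data contract behind an allotaxonograph; the 45°
rotation seen in published instruments is a display transform.

## Contagiograms

For a target n-gram, monthly organic and retweet fractions
$f_{OT} + f_{RT} = 1$ are computed from summed daily counts; a month is
*amplified* when $f_{RT} > 1/2$ strictly. The heatmap statistic compares
retweet odds against the background corpus per (weekday, month) cell:

$$R = \frac{c_{RT}/c_{OT}}{C_{RT}/C_{OT}},$$

with counts summed over the cell's days before ratios are formed (ratio
of sums, not mean of ratios, to avoid zero-day instability). Cells with
any zero count are reported as undefined with their counts attached —
clamping would fabricate amplification values. The (weekday × month)
grid is one of several defensible periodizations; it is what the
exported table encodes, and the cell aggregation is documented so other
grids can be derived from the daily ledgers.

The rank panel smooths $\log_{10}$ rank with a trailing 30-day mean
(ranks live on a log scale, so smoothing the logarithm is the faithful
choice) and records per-ISO-week min–max bands. A balance crossing is
declared at the first month beginning a run of at least three
consecutive amplified months; the three-month requirement guards against
single-month noise near the 1/2 boundary and is configurable.

## The synthetic stream

The generator emulates the statistical skeleton of a decade-scale
10%-style feed. Everything is driven by one integer seed; identical
configurations produce byte-identical streams.

| Parameter | Default | Why |
|---|---|---|
| window | 2010-01-01 … 2019-12-31 | a decade of daily data |
| `messages_per_day` | 1000 | desk-scale stand-in for a platform feed |
| `vocab_size` | 50,000 | much larger than the daily token flow, so daily rank distributions have a realistic heavy-tailed dynamic range |
| `zipf_exponent` | 1.0 | classic Zipf background |
| `pi_start` → `pi_end` | $10^{-4}$ → $10^{-2}$ | anchor prevalence grows two orders of magnitude, log-linearly |
| events | annual awareness days + 6 irregular tragedies | awareness boosts ×25 (late January) and ×10 (October), tragedies ×15, decaying with half-lives of 1.5–3 days |
| `sentiment_means` | baseline 5.5, awareness 6.5, tragedy 4.0 (sd 0.75) | regimes shift the anchor-topic word distribution toward happy or sad lexicon words, the directions word shifts must recover |
| `topic_lexicon_frac` | 0.5 | fraction of topic-message tokens drawn from the lexicon; the rest are background draws, diluting the signal realistically |
| retweet schedule | $0.25 \to 0.75$, tanh with 60-day scale, crossing 1/2 on 2017-07-01 | the platform-wide shift toward sharing, with a well-defined planted crossing date |
| `anchor_retweet_odds_boost` | 1.5 | anchor messages are shared more than background; the planted heatmap ratio equals this factor exactly because the boost is applied to odds |
| message length | uniform 5–25 tokens | keeps per-day token totals stable for rank comparisons |

Topic messages contain the anchor phrase as an adjacent token pair at a
uniform position; their remaining tokens mix regime-weighted lexicon
draws (weights $\propto$ a Gaussian in the word's happiness score,
centered on the regime mean) with background draws. Background messages
draw only from the background vocabulary, which excludes the anchor's
constituent tokens — so the anchored subset is exact by construction, an
invariant the tests exploit. Retweets are generated as fresh flagged
samples rather than copies of earlier messages: every downstream
statistic uses only the flag and the text, never retweet provenance.
Event boosts multiply the prevalence and are capped at 1 so probabilities
stay valid. The day's regime is the kind of the event with the strongest
active boost (above a small activity floor), else baseline.

The ground-truth record (per-day scheduled and realized prevalence and
retweet fraction, regimes, events, sentiment means, and the scheduled
month at which the anchor's retweet odds cross 1/2) is what recovery
tests compare against.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about real data: user graphs and follower
cascades, hashtag co-evolution, bot behavior, multilingual text, emoji,
message-length/topic correlations, and real lexical semantics (topic
words are sentiment-weighted draws, not discourse). Recovery of planted
structure shows the estimators are correct and well-calibrated, not that
any particular real-world corpus behaves this way.

## Numerical choices and degenerate inputs

* Fractional (average) ranks everywhere; rank sums are checked to
  $10^{-9}$ and frequencies to $10^{-12}$.
* Counting groups n-grams by integer token ids with positional encoding
  (base-$K$ in doubles), falling back to string keys when $K^n$ would
  exceed $2^{53}$; both paths are oracle-tested.
* Missing data: absent ranks are `NA`; ambient happiness of a day with
  no lexicon-matched tokens is `NA`; smoothing windows with fewer than
  half their points available are `NA`; undefined heatmap cells are `NA`
  with counts attached. No sentinels anywhere.
* Empty inputs error early with plain messages (empty distribution,
  empty anchor, empty systems, zero-message days).
* Degenerate schedules are legal: zero prevalence yields an anchor-free
  stream; a constant retweet schedule yields no crossing (`NA`).
* The background corpus for divergence is a systematic 1-in-$k$
  subsample of the stream; messages are exchangeable within a day, so
  systematic sampling is unbiased here and — unlike a random subsample —
  consumes no random numbers, keeping the generator's RNG stream
  identical whether or not a pipeline runs around it.

## Problem sizes

The test suite exercises the full default decade (3,652 days × 1,000
messages/day ≈ 3.65M messages) once, end to end, and uses smaller
streams (hundreds to thousands of messages) for the property-based
checks: brute-force recount equivalence on 100 random toy streams,
word-shift conservation on 500 random corpus pairs, divergence-oracle
equality on an exhaustive sweep of systems with up to 20 types, and
crossing recovery on 20 seeded 18-month runs. These sizes were chosen so
each property is tested at full strictness while the suite stays quick
to run.

## Known limitations

Dictionary-based sentiment scoring cannot see negation, sarcasm, or
context; ambient happiness is a lexical average, not an emotion
measurement. The bundled lexicon is a small synthetic fixture for
testing and simulation — real analyses should load a crowdsourced
instrument. Tokenization is whitespace-based and language-agnostic:
no hashtag segmentation, stemming, or emoji handling. The divergence
module implements only rank-turbulence divergence, not
probability-turbulence or other families. All day boundaries are UTC
calendar days.
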