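---
title: "Methods: geolocation, aberration detection and evaluation in tweetsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geolocation, aberration detection and evaluation in tweetsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweetsignal)
library(tibble)
```

## What the package models

`tweetsignal` is an offline, fully testable implementation of an event-based
surveillance pipeline for short social-media posts. Operational systems of
this kind monitor the volume of posts per disease topic and region and raise
an alert when today's count exceeds what recent history predicts. The package
covers the four processing stages — geolocation, aggregation, detection,
alerting — plus the statistics used to evaluate such a system against manual
monitoring, and a synthetic stream generator so the whole loop can be
exercised without any platform API access.

## The synthetic stream generator

Real post streams are not redistributable, so the generator is a first-class
module rather than a test fixture. It emulates:

* **daily volume**: per topic and country, daily original-post counts are
  negative binomial with mean $\lambda$ and dispersion $k$
  (`dispersion = Inf` gives Poisson). Real tweet counts are overdispersed,
  which is why the NB family was chosen; $k$ is a single knob from
  near-Poisson to strongly clumped.
* **post structure**: fixed fractions of retweets and quotes (defaults 0.15
  and 0.05), a trusted-account fraction (0.10), and a per-post probability
  that the text embeds a gazetteer place name verbatim (default 0.8). Posts
  mention places of the stream's own country where the gazetteer covers it,
  so injected bursts surface in that country's count series.
* **templated texts** in the four study languages (EN/FR/ES/PT), of the form
  `"<topic> cases reported in <PlaceName>"`. Because the embedded place is
  recorded in `sim_country`, geolocation accuracy can be measured exactly
  (closed loop). Retweets and quotes carry the place in their `origin_text`
  only, which exercises the fallback search order.
* **outbreaks**: an `outbreak_spec()` multiplies one topic-country rate by a
  factor `magnitude` over a date window — ground truth for power studies.

What the generator deliberately does *not* emulate: vocabulary drift, bot
traffic, sarcasm/negation, multi-place texts, person names that look like
places, or geographic spelling noise. Passing closed-loop tests therefore
demonstrate that the machinery is correct, not that real-world accuracy will
match; the worked-example statistics bundled with the package show how far
real streams sit from the clean synthetic setting (about 30% national
geolocation accuracy in the field versus 100% in the closed loop).

Timestamps are uniform within the UTC day; detection works at daily
granularity, so intraday structure is irrelevant. Day boundaries are UTC
throughout.

## Two-step geolocation

**Step 1 — candidate extraction.** A trainable scorer decides which tokens
look like place words. The default is a ridge-penalised logistic regression
on character 2–4-gram indicators, fitted with IRLS solved in the observation
space, so it remains exact and well defined even with one training word per
class. Positives are the gazetteer's name tokens (3+ characters); negatives
are bundled stop-word and common-word lists per language, including domain
vocabulary (outbreak, cases, vaccine, disease names) so that topic words do
not leak into candidate spans. Tokens scoring at or above
`min_candidate_score` (default 0.5; trained positives sit near 1, trained
negatives near 0, unknown tokens near the intercept) form maximal runs, so
"Ciudad Real" is one span. At match time, spans separated by exactly one
rejected token are additionally tried as a bridged span, because compound
names often contain a connective the classifier rightly rejects
("Castilla-La Mancha", "Île-de-France").

**Step 2 — vector-space matching.** Candidates are scored against a
GeoNames-format gazetteer with a term-weighted similarity:

$$\mathrm{score}(q, e) \;=\; \frac{\sum_{t \in q \cap e} \mathrm{idf}(t)\, b_f}{\sqrt{|e|}}
\cdot \frac{|q \cap e|}{|q|}
\cdot \bigl(1 + w_p \log_{10}(1 + \mathrm{pop}_e)\bigr)
\cdot b_x^{[q \equiv e]}$$

with $\mathrm{idf}(t) = 1 + \log(N/\mathrm{df}(t))$, field boosts $b_f$ (2
for primary-name tokens, 1 for alternate names), entry-length normalisation
$\sqrt{|e|}$, query coverage $|q \cap e|/|q|$, a population boost
($w_p = 0.1$) and an exact-full-name boost ($b_x = 2$). Ties break by higher
population, then lower entry id. All constants are arguments of
`build_index()`.

The scale is calibrated so that, on a realistically sized index, an exact
match of a well-known place scores well above the default acceptance
threshold of 10 (Paris ≈ 29, São Paulo ≈ 43) while a single common token
matching only part of a compound name stays below it ("real" →
Ciudad Real ≈ 9.3). Acceptance is strict (`score > min_score`), so raising
the threshold can only remove acceptances — the monotonicity that drives
the accuracy/sensitivity trade-off users control with this knob.

**Search order.** For the post location: the text first, then (for retweets
and quotes only) the origin text. For the account location: location at
posting time, then the self-declared location, then the profile field, first
accepted match wins; user-location fields are additionally matched as a
whole string, since they are already location metadata rather than free
text. Offsets are 0-based half-open; tokens are Unicode letter/digit runs,
casefolded, with URLs and @-mentions masked, `#` stripped, and hyphens
treated as separators.

A known, accepted limitation: person names are not distinguished from place
words, so a text about a head of state may geolocate to whatever gazetteer
entry shares tokens with the name. Fixing this would require a person
gazetteer, which is out of scope.

## Aggregation

Each record counts once at each regional level of its resolved location
(tweet location preferred, account location as fallback): country,
continent, the pan-American super-region "America" where applicable, and
WORLD. Records with no accepted location count under WORLD only — so WORLD
totals always equal the number of records, and country series can only
undercount. Retweets and quotes are excluded from `count_original`, the
series used for detection (a configuration switch can re-include them).
Missing days are zero-filled so baselines see true zeroes.

## Detection: a modified EARS threshold

For each topic-by-region series, the baseline is the `baseline_days`
(default 7) days immediately before the evaluation date — or the same
weekday of previous weeks when `same_weekday_only` is set. The threshold is
the upper $1-\alpha$ prediction bound for one new observation under a
normal model with unknown mean and variance:

$$U \;=\; \hat\mu_w + t_{1-\alpha,\,N-1}\; \hat\sigma_w \sqrt{1 + 1/N}$$

A signal fires when the observed count **strictly** exceeds $U$. The
Student-t form with the $\sqrt{1+1/N}$ inflation was chosen over a plain
quantile because it has correct finite-sample coverage at $N = 7$; the
acceptance suite verifies the empirical false-alert rate on Poisson(50)
null series is within Monte-Carlo error of the nominal $\alpha$.

**Outlier downweighting.** Before the threshold is computed, baseline values
whose standardised residual $r_i = (y_i - \hat\mu)/\hat\sigma$ exceeds a
cut-off $c$ are given weight $(c/r_i)^2$; $c$ is 3, 2 or 1.5 for the low,
medium and high settings. Flagging is one-sided (high outliers only): the
purpose is to stop a past spike from inflating the threshold and masking a
new event, and downweighting low days would raise thresholds instead.
$\hat\mu_w$ and $\hat\sigma_w$ use the frequency-weight convention
(denominator $\sum w - 1$). A zero-variance baseline leaves all weights at
1, and the threshold then equals the mean — so a flat history of zeroes
alerts on the first post, deliberately: single-post signals are a feature
of this detector family.

Degenerate inputs: fewer than 2 baseline values is an error; $\alpha$ is
validated in (0, 1) at configuration time, before any processing; the
threshold is floored at the expected value so pathological $\alpha > 0.5$
settings cannot produce thresholds below the mean.

Alerts carry date, run hour, topic, region, the k most frequent non-stop
words (k = 20 by default, ties broken alphabetically for determinism), the
observed count, the percentage of trusted-account posts, and the detection
configuration. They are written as CSV and JSON Lines; file output replaces
e-mail dispatch.

## Evaluation statistics

* **Confusion metrics** (`confusion_metrics()`): standard formulas;
  NPV is $tn/(tn+fn)$. Counts may be fractional because metrics are
  averaged across two raters. Zero denominators yield `NA`, never errors.
* **Annotation scoring** (`geolocation_accuracy()`): a rater's gold location
  defines the positive class; the standard TP/FN/FP/TN assignment is used,
  and per-tweet accuracy is 1 only when predicted and gold locations agree
  at the requested level (national = country, subnational = country +
  first-level division).
* **PPV**: specific = events / evaluated signals; general spreads the same
  numerator over all alerts including never-evaluated ones, so
  $PPV_g \le PPV_s$ always.
* **IRA**: with no gold standard of all true events, the share of jointly
  evaluated signals found by an arm acts as a relative sensitivity.
* **Wald intervals** on the percentage scale, clipped to [0, 100]. The
  normal-approximation family reproduces the worked example's printed
  intervals to one decimal, which is why it was chosen over score or exact
  intervals.
* **Timeliness**: unique events are formed by grouping validated events on
  (topic, manually assigned subtopic), keeping the earliest validation time
  per arm; paired differences (automated − manual, hours; negative =
  automated earlier) are summarised by median and linearly interpolated
  quartiles.
* **Wilcoxon signed-rank**, one-sided: zeroes dropped, midranks for ties,
  exact distribution for tie-free $n \le 15$, otherwise a normal
  approximation with tie and continuity correction. Tests verify the exact
  branch against brute-force sign enumeration and both branches against the
  reference implementation in `stats`.

Display rounding is half-up to one decimal and applied only at
presentation; all computation keeps full precision.

## Problem sizes and numerical choices

The shipped experiments use sizes a desk study can afford while keeping
Monte-Carlo error small: 10,000 simulated null days for calibration
(3 standard errors ≈ ±0.0065 around α = 0.05), 200 seeded runs for
outbreak-detection power, a ~500-record corpus for threshold monotonicity,
and a 31-entry gazetteer whose score distribution spans roughly 5–50. The
classifier's ridge penalty (λ = 1) and n-gram range (2–4) were fixed once;
training is deterministic, so no seed sensitivity exists anywhere in the
geolocation path. All remaining randomness flows through a single integer
seed per generator call.

## Known limitations

* The gazetteer fixture is small; idf weights on a full GeoNames dump will
  spread scores differently, and the calibration constants in
  `build_index()` are the intended adjustment point.
* Candidate bridging spans at most one rejected token; names with two
  consecutive connectives would need a wider bridge.
* Alerts are not deduplicated across runs within a day; the run hour is
  recorded and scheduling is the caller's choice.
* The evaluation module treats triage labels (signal/event/false signal) as
  inputs; it does not model the human screening criteria that produce them.
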