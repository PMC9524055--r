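# Aggregate counts from the published field evaluation of an operational
# Twitter-based early-warning deployment (six weeks of alerts reviewed by two
# epidemic-intelligence experts, plus 1,200 manually geolocated tweets).
# These counts are inputs to the worked example: the package recomputes every
# evaluation statistic from them.
geolocation:
  n_tweets: 1200
  n_retained_score_over_10: 804
  correct_hits:
    national_all: 361
    subnational_all: 311
    national_score_over_10: 292
    subnational_score_over_10: 283
signal_review:
  alerts_total: 11313
  signals_evaluated: 448
  events: 334
  false_signals: 114
  covid_events: 48
  covid_false_signals: 15
comparison:
  signals_evaluated_total: 570
  detected_automated: 448
  detected_manual: 273
ci_level: 0.95
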