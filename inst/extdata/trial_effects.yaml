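# Published 6-month SF-36 physical-function improvements after total hip
# (THR) and total knee (TKR) replacement, from three prospective cohorts.
# pre = mean pre-intervention SF-36 physical function score (0-100 points),
# improvement = mean gain at 6 months, n_pre / n_post = sample sizes.
- study: Quintana et al.
  procedure: THR
  age_stratum: adult
  pre: 17.98
  improvement: 34.44
  n_pre: 575
  n_post: 434
- study: Quintana et al.
  procedure: TKR
  age_stratum: adult
  pre: 19.49
  improvement: 25.79
  n_pre: 557
  n_post: 414
- study: Jones et al. (Capital Health)
  procedure: TKR
  age_stratum: adult
  pre: 21.0
  improvement: 23.8
  n_pre: 276
  n_post: 273
- study: Jones et al. (Edmonton)
  procedure: THR
  age_stratum: "<80"
  pre: 20
  improvement: 30
  n_pre: 163
  n_post: 163
- study: Jones et al. (Edmonton)
  procedure: THR
  age_stratum: ">=80"
  pre: 13
  improvement: 26
  n_pre: 34
  n_post: 34
- study: Jones et al. (Edmonton)
  procedure: TKR
  age_stratum: "<80"
  pre: 21
  improvement: 26
  n_pre: 221
  n_post: 221
- study: Jones et al. (Edmonton)
  procedure: TKR
  age_stratum: ">=80"
  pre: 17
  improvement: 18
  n_pre: 35
  n_post: 36
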