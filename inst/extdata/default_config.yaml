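schema_version: 1
population:
  'n': 1259
  seed: 1
  tumor_probs:
    breast: 0.07
    colon: 0.01
    endometrial: 0.07
    gastric: 0.01
    hepatic: 0.01
    lung: 0.48
    ovarian: 0.28
    pancreatic: 0.04
    sarcoma: 0.03
  sex_given_tumor:
    breast: 0.0
    colon: 0.545454545454545
    endometrial: 0.0
    gastric: 0.714285714285714
    hepatic: 0.5625
    lung: 0.593063583815029
    ovarian: 0.0
    pancreatic: 0.651515151515151
    sarcoma: 0.471428571428571
  origin_probs:
    European: 0.96
    Sub-Saharan African: 0.02
    East Asian: 0.02
  ecog_probs:
    '0': 0.368421052631579
    '1': 0.578947368421053
    '2': 0.052631578947368
  age_targets:
    male_nonsarcoma:
      mean: 62.299999999999997
      sd: 9.300000000000001
    male_sarcoma:
      mean: 62.299999999999997
      sd: 9.300000000000001
    female_nonsarcoma:
      mean: 59.100000000000001
      sd: 11.199999999999999
    female_sarcoma:
      mean: 59.100000000000001
      sd: 11.199999999999999
  age_bounds:
  - 18.0
  - 95.0
coefficients:
  htc_scale: linear
  stages:
  - id: 1
    response: height
    scale: linear
    intercept: 179.900000000000006
    terms:
    - kind: numeric
      var: age
      coef: -0.16
    - kind: indicator
      var: sex
      coef: -12.81
      levels:
      - female
    - kind: indicator
      var: origin
      coef: 6.42
      levels:
      - Sub-Saharan African
    - kind: indicator
      var: origin
      coef: 3.83
      levels:
      - European
  - id: 2
    response: weight
    scale: log
    intercept: 2.1
    terms:
    - kind: numeric
      var: height
      coef: 0.012
    - kind: interaction
      var: height
      coef: -0.004
      by: sex
      by_levels:
      - female
    - kind: indicator
      var: sex
      coef: 0.562
      levels:
      - female
    - kind: indicator
      var: origin
      coef: 0.262
      levels:
      - Sub-Saharan African
    - kind: indicator
      var: origin
      coef: 0.144
      levels:
      - European
  - id: 3
    response: aag
    scale: log
    intercept: 4.32
    terms:
    - kind: indicator
      var: ecog
      coef: 0.161
      levels:
      - '1'
    - kind: indicator
      var: ecog
      coef: 0.449
      levels:
      - '2'
    - kind: indicator
      var: origin
      coef: 0.634
      levels:
      - Sub-Saharan African
    - kind: indicator
      var: origin
      coef: 0.37
      levels:
      - European
    - kind: indicator
      var: tumor
      coef: 0.622
      levels:
      - ovarian
  - id: 4
    response: albumin
    scale: linear
    intercept: 5.546
    terms:
    - kind: numeric
      var: age
      coef: -0.004
    - kind: numeric
      var: aag
      coef: -0.292
      transform: log
    - kind: indicator
      var: ecog
      coef: -0.128
      levels:
      - '1'
    - kind: indicator
      var: ecog
      coef: -0.429
      levels:
      - '2'
    - kind: indicator
      var: origin
      coef: 0.276
      levels:
      - Sub-Saharan African
    - kind: indicator
      var: origin
      coef: 0.248
      levels:
      - European
    - kind: indicator
      var: tumor
      coef: -0.339
      levels:
      - pancreatic
      - hepatic
      - gastric
  - id: 5
    response: hb
    scale: linear
    intercept: 12.35
    terms:
    - kind: numeric
      var: albumin
      coef: 0.575
    - kind: numeric
      var: aag
      coef: -0.793
      transform: log
    - kind: indicator
      var: sex
      coef: -0.68
      levels:
      - female
  - id: 6
    response: nl_ratio
    scale: log
    intercept: 1.47
    terms:
    - kind: numeric
      var: aag
      coef: -0.0073
      transform: log
    - kind: numeric
      var: albumin
      coef: -0.16
  - id: 7
    response: pl_ratio
    scale: log
    intercept: 5.52
    terms:
    - kind: numeric
      var: hb
      coef: -0.057
    - kind: numeric
      var: aag
      coef: 0.0016
    - kind: numeric
      var: nl_ratio
      coef: 0.0622
    - kind: indicator
      var: tumor
      coef: -0.204
      levels:
      - pancreatic
      - hepatic
      - gastric
  - id: 8
    response: crp
    scale: log
    intercept: 1.394
    terms:
    - kind: numeric
      var: pl_ratio
      coef: 0.002
    - kind: indicator
      var: ecog
      coef: 0.368
      levels:
      - '1'
    - kind: indicator
      var: ecog
      coef: 0.598
      levels:
      - '2'
    - kind: indicator
      var: tumor
      coef: -2.22
      levels:
      - breast
  - id: 9
    response: ldh
    scale: log
    intercept: 5.709
    terms:
    - kind: numeric
      var: crp
      coef: 0.001
  - id: 10
    response: htc
    scale: linear
    intercept: 5.93
    terms:
    - kind: numeric
      var: aag
      coef: 0.04
      transform: log
    - kind: numeric
      var: hb
      coef: 2.515
residuals:
  sds:
    height: 4.0
    weight: 0.1
    aag: 0.1
    albumin: 0.3
    hb: 1.0
    nl_ratio: 0.1
    pl_ratio: 0.1
    crp: 0.1
    ldh: 0.1
    htc: 2.0
  bounds:
    height:
    - 0.0
    - .inf
    weight:
    - 0.0
    - .inf
    aag:
    - 0.0
    - .inf
    albumin:
    - 1.0
    - 6.0
    hb:
    - 5.0
    - 20.0
    nl_ratio:
    - 0.0
    - .inf
    pl_ratio:
    - 0.0
    - .inf
    crp:
    - 0.0
    - .inf
    ldh:
    - 0.0
    - .inf
    htc:
    - 15.0
    - 60.0
  policy:
    height: resample
    weight: resample
    aag: resample
    albumin: resample
    hb: resample
    nl_ratio: resample
    pl_ratio: resample
    crp: resample
    ldh: resample
    htc: resample
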