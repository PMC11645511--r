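'n': 6997
persona_mix:
  attentive: 0.816
  straightliner: 0.02
  speeder: 0.0
  misrepresenter: 0.144
  copier: 0.02
fake_endorse_prob: 0.9
overendorse_prob: 0.8
miss_rate: 0.02
incomplete_rate: 0.035
misrep_straightline_prob: 0.3
demo_marginals:
  age:
    18-29: 0.1988012
    30-44: 0.2587413
    45-60: 0.2397602
    60+: 0.3026973
  gender:
    female: 0.507
    male: 0.493
  race_ethnicity:
    hispanic: 0.1721722
    multiracial: 0.014014
    nh_black: 0.1201201
    nh_white: 0.6206206
    nh_other: 0.0730731
  education:
    no_hs: 0.096
    hs_grad: 0.292
    some_college: 0.264
    bachelor: 0.218
    masters_plus: 0.13
  income:
    lt_10k: 0.036
    10k_50k: 0.249
    50k_100k: 0.286
    ge_100k: 0.429
  region:
    northeast: 0.174
    midwest: 0.206
    south: 0.383
    west: 0.237
demo_bias:
  age:
    18-29: 0.98
    30-44: 1.95
    45-60: 0.87
    60+: 0.27
  gender:
    female: 0.89
    male: 1.07
  race_ethnicity:
    hispanic: 0.82
    multiracial: 1.5
    nh_black: 0.69
    nh_white: 1.11
    nh_other: 0.78
  education:
    no_hs: 0.032
    hs_grad: 0.27
    some_college: 0.91
    bachelor: 2.23
    masters_plus: 1.36
  income:
    lt_10k: 1.2
    10k_50k: 1.7
    50k_100k: 1.39
    ge_100k: 0.29
  region:
    northeast: 1.01
    midwest: 0.95
    south: 1.03
    west: 0.94
seed: 1
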