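age:
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
source: national benchmark proportions (CPS-ASEC-style March 2022 column)
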