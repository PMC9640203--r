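n_registered: 393.0
p_login: 0.605598
p_target_age: 0.5336134
target_age:
- 13.0
- 24.0
nontarget_age:
- 25.0
- 64.0
gender_mix:
  female: 0.709
  male: 0.241
  another_gender: 0.05
ethnicity_mix:
  nz_european: 0.472
  maori: 0.22
  pacific: 0.1
  asian: 0.12
  other_unspecified: 0.088
mu_pre: 5.1
sd_pre: 2.6
effect_delta: 0.8
sd_noise: 1.5
p_reach_outro: 0.6377953
p_complete_outro: 0.3703704
p_return: 0.2440945
seed: 1

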