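# Illness-death model rates for dementia in German males.
# Calendar time is measured in years since `time_origin`.
time_origin: 1960
incidence:            # i(a) = exp(-12.8 + 0.11 a), a >= 50, no secular trend
  beta0: -12.8
  beta_age: 0.11
  beta_time: 0.0
  min_age: 50
mortality_healthy:    # m0(t, a) = exp(-9.0 + 0.085 a - t ln 1.01)
  beta0: -9.0
  beta_age: 0.085
  beta_time: -0.00995033085316808   # -ln(1.01)
relative_mortality:   # m1 = R m0, constant over disease duration
  constant: 2.63
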