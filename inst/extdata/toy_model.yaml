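# Declarative model description equivalent to the built-in three-state
# model (see ?model_from_config).
name: toy_cfg
states: [x1, x2, x3]
input: u
input_observable: y4
parameters:
  dynamic: [k1, km1, k2, km2]
rhs:
  x1: -k1 * u * x1 + km1 * x2
  x2: k1 * u * x1 - km1 * x2 - k2 * x2 + km2 * x3
  x3: k2 * x2 - km2 * x3
observations:
  y1: log10(x1)
  y2: log10(x2)
  y3: log10(x3)
  y4: log10(u)
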