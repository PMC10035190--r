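# log-rate priors: midpoint of a generous plausible range, range/4 as sd
parameters:
  k1: {mean: -1.151, sd: 1.727, lower: -4.605, upper: 2.303}
  k2: {mean: -1.151, sd: 1.727, lower: -4.605, upper: 2.303}
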