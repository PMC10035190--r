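# two-state decay chain A -> B -> (out), equivalent to exemplar "decay2"
initial: {A: 1.0, B: 0.25}
observed: [A, B]
reactions:
  - {from: A, to: B, param: k1, name: v_A_B}
  - {from: B, param: k2, name: v_B_out}
fluxes:
  conversion: v_A_B
  efflux: v_B_out
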