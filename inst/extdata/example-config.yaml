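# overridable knobs; anything omitted keeps the package default
generator:
  tol: 0.25
adaptive:
  up_step: 0.5
complexity:
  sigmoid_beta: 2
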