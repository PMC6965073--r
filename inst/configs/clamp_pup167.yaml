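# voltage-clamped pulse train, P_up x1.67 (beta-AS level)
analysis: clamp
variant: mTP06b
overrides:
  Pup: 1.67
duration_min: 10
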