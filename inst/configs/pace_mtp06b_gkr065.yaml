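# g_Kr-reduced mTP06b paced at 0.2 Hz (EAD regime)
analysis: pace
variant: mTP06b
overrides:
  gKr: 0.65
fix_Ki: true
CL: 5000
n_beats: 30
stop: converge
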