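# critical normalized g_Kr for EAD onset, mTP06b, 0.2-Hz pacing
analysis: critical
variant: mTP06b
fix_Ki: true
CL: 5000
axis: gKr
bracket: [0.74, 0.80]
resolution: 0.001
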