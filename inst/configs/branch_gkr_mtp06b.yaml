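# non-paced equilibrium branches vs normalized g_Kr (K_i fixed)
analysis: branch
variant: mTP06b
fix_Ki: true
axis: gKr
from: 1.0
to: 0.1
by: -0.05
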