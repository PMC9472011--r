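baseline: 60.0
fx: 1200.0
fy: 1200.0
width: 640.0
height: 480.0
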