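convention: standard (distal) Denavit-Hartenberg; mm and radians
links:
- a: 0.0
  alpha: 1.5707963
  d: 180.0
  theta0: 0.0
  limits:
  - -3.1415927
  - 3.1415927
- a: 250.0
  alpha: 0.0
  d: 0.0
  theta0: 0.0
  limits:
  - -2.2
  - 2.2
- a: 60.0
  alpha: 1.5707963
  d: 0.0
  theta0: 1.5707963
  limits:
  - -2.6
  - 2.6
- a: 0.0
  alpha: -1.5707963
  d: 230.0
  theta0: 0.0
  limits:
  - -3.1415927
  - 3.1415927
- a: 0.0
  alpha: 1.5707963
  d: 0.0
  theta0: 0.0
  limits:
  - -2.0
  - 2.0
- a: 0.0
  alpha: 0.0
  d: 80.0
  theta0: 0.0
  limits:
  - -3.1415927
  - 3.1415927
base:
- 1.0
- 0.0
- 0.0
- 0.0
- 0.0
- 1.0
- 0.0
- 0.0
- 0.0
- 0.0
- 1.0
- 0.0
- 0.0
- 0.0
- 0.0
- 1.0
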