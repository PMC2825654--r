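background:
  lo:
  - -5.0
  - -5.0
  - -2.5
  hi:
  - 5.0
  - 5.0
  - 2.5
  material:
    name: water
    mu_t: 0.028
    mu_s: 0.182
    beta: 0.076923076923077
inclusions:
- lo:
  - -3.0
  - 2.0
  - -0.5
  hi:
  - -2.0
  - 3.0
  - 0.5
  material:
    name: cube1
    mu_t: 0.028
    mu_s: 0.182
    beta: 0.019230769230769
- lo:
  - 2.0
  - 2.0
  - -0.5
  hi:
  - 3.0
  - 3.0
  - 0.5
  material:
    name: cube2
    mu_t: 0.028
    mu_s: 0.182
    beta: 0.038461538461538
- lo:
  - -3.0
  - -3.0
  - -0.5
  hi:
  - -2.0
  - -2.0
  - 0.5
  material:
    name: cube3
    mu_t: 0.028
    mu_s: 0.182
    beta: 0.142857142857143
- lo:
  - 2.0
  - -3.0
  - -0.5
  hi:
  - 3.0
  - -2.0
  - 0.5
  material:
    name: cube4
    mu_t: 0.028
    mu_s: 0.182
    beta: 0.285714285714286

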