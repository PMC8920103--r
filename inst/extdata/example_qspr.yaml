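# Example linear phospholipophilicity model (illustrative coefficients only;
# supply your own, e.g. from the published IAM retention web service).
phase: MG
intercept: -0.62
terms:
  - descriptor: miLogP
    coefficient: 0.58
  - descriptor: HLB_M
    coefficient: -0.04
metadata:
  n: 205
  r2: 0.90
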