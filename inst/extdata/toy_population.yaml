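# Synthetic population: two focal measures (X, Y) and two criteria (A, B)
# with a known correlation structure; used by the `generate` subcommand
# examples and the test suite.
labels: [X, Y, A, B]
corr:
  - [1.00, 0.40, 0.30, 0.10]
  - [0.40, 1.00, 0.25, 0.20]
  - [0.30, 0.25, 1.00, 0.05]
  - [0.10, 0.20, 0.05, 1.00]
reliabilities: [0.90, 0.85, 0.80, 0.80]
n: 500
seed: 20260924
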