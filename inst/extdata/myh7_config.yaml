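frequency:
  ba1: 0.001
  bs1: 0.0002
  pm2: 4.0e-05
  confidence: 0.95
  min_an: 2000.0
  method: poisson
cohorts:
  cases:
    AFR: 500.0
    NFE: 2500.0
  controls:
    AFR: 5203.0
    NFE: 33370.0
  control_carriers: 2.0
derivation:
  ba1:
    prevalence: 0.005
    contribution: 0.106
    penetrance: 0.3
  bs1:
    prevalence: 0.005
    contribution: 0.02
    penetrance: 0.3
  pm2:
    prevalence: 0.002
    contribution: 0.02
    penetrance: 0.5
registry_overrides: ~
combining:
  pathogenic:
  - vs: 1.0
    s: 1.0
  - vs: 1.0
    m: 2.0
  - vs: 1.0
    m: 1.0
    p: 1.0
  - vs: 1.0
    p: 2.0
  - s: 2.0
  - s: 1.0
    m: 3.0
  - s: 1.0
    m: 2.0
    p: 2.0
  - s: 1.0
    m: 1.0
    p: 4.0
  likely_pathogenic:
  - vs: 1.0
    m: 1.0
  - s: 1.0
    m: 1.0
  - s: 1.0
    p: 2.0
  - m: 3.0
  - m: 2.0
    p: 2.0
  - m: 1.0
    p: 4.0
  benign:
  - sa: 1.0
  - bs: 2.0
  likely_benign:
  - bs: 1.0
    bp: 1.0
  - bp: 2.0
  bs1_alone_likely_benign: yes
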