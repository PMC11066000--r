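rotarod:
  thresholds:
  - 50.0
  - 100.0
  - 200.0
  - 300.0
  strict:
  - yes
  - yes
  - yes
  - no
  direction: asc
openfield:
  thresholds:
  - 300.0
  - 500.0
  - 800.0
  - 1000.0
  strict:
  - no
  - no
  - no
  - yes
  direction: asc
bwl:
  thresholds:
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  strict:
  - no
  - no
  - no
  - yes
  direction: desc
severity_cuts:
- 6
- 10
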