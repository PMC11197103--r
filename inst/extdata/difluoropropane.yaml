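spins:
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 19F
- 19F
shifts_ppm:
- 4.52
- 4.52
- 1.95
- 1.95
- 4.52
- 4.52
- -221.0
- -221.0
base_frequency_mhz: 500.0
j_hz:
- - 0.0
  - -10.1
  - 5.9
  - 5.9
  - 0.0
  - 0.0
  - 47.200000000000003
  - 0.0
- - -10.1
  - 0.0
  - 5.9
  - 5.9
  - 0.0
  - 0.0
  - 47.200000000000003
  - 0.0
- - 5.9
  - 5.9
  - 0.0
  - -14.5
  - 5.9
  - 5.9
  - 23.5
  - 23.5
- - 5.9
  - 5.9
  - -14.5
  - 0.0
  - 5.9
  - 5.9
  - 23.5
  - 23.5
- - 0.0
  - 0.0
  - 5.9
  - 5.9
  - 0.0
  - -10.1
  - 0.0
  - 47.200000000000003
- - 0.0
  - 0.0
  - 5.9
  - 5.9
  - -10.1
  - 0.0
  - 0.0
  - 47.200000000000003
- - 47.200000000000003
  - 47.200000000000003
  - 23.5
  - 23.5
  - 0.0
  - 0.0
  - 0.0
  - 2.8
- - 0.0
  - 0.0
  - 23.5
  - 23.5
  - 47.200000000000003
  - 47.200000000000003
  - 2.8
  - 0.0
equivalences:
- - 1
  - 2
  - 5
  - 6
- - 3
  - 4
- - 7
  - 8
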