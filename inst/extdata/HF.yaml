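spins:
- 1H
- 19F
shifts_ppm:
- 4.5
- -180.0
base_frequency_mhz: 500.0
j_hz:
- - 0.0
  - 48.0
- - 48.0
  - 0.0
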