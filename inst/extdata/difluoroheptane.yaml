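spins:
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 1H
- 19F
- 19F
shifts_ppm:
- 0.96
- 0.96
- 0.96
- 1.62
- 1.7
- 4.55
- 1.78
- 1.86
- 4.55
- 1.62
- 1.7
- 0.96
- 0.96
- 0.96
- -184.5
- -184.5
base_frequency_mhz: 500.0
j_hz:
- - 0.0
  - 12.0
  - 12.0
  - 7.4
  - 7.4
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- - 12.0
  - 0.0
  - 12.0
  - 7.4
  - 7.4
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- - 12.0
  - 12.0
  - 0.0
  - 7.4
  - 7.4
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
- - 7.4
  - 7.4
  - 7.4
  - 0.0
  - -13.9
  - 3.4
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 18.0
  - 0.0
- - 7.4
  - 7.4
  - 7.4
  - -13.9
  - 0.0
  - 8.800000000000001
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 27.5
  - 0.0
- - 0.0
  - 0.0
  - 0.0
  - 3.4
  - 8.800000000000001
  - 0.0
  - 9.1
  - 2.9
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 48.600000000000001
  - 2.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 9.1
  - 0.0
  - -14.800000000000001
  - 2.9
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 21.0
  - 12.5
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 2.9
  - -14.800000000000001
  - 0.0
  - 9.1
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 12.5
  - 21.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 2.9
  - 9.1
  - 0.0
  - 3.4
  - 8.800000000000001
  - 0.0
  - 0.0
  - 0.0
  - 2.0
  - 48.600000000000001
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 3.4
  - 0.0
  - -13.9
  - 7.4
  - 7.4
  - 7.4
  - 0.0
  - 18.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 8.800000000000001
  - -13.9
  - 0.0
  - 7.4
  - 7.4
  - 7.4
  - 0.0
  - 27.5
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 7.4
  - 7.4
  - 0.0
  - 12.0
  - 12.0
  - 0.0
  - 0.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 7.4
  - 7.4
  - 12.0
  - 0.0
  - 12.0
  - 0.0
  - 0.0
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 7.4
  - 7.4
  - 12.0
  - 12.0
  - 0.0
  - 0.0
  - 0.0
- - 0.0
  - 0.0
  - 0.0
  - 18.0
  - 27.5
  - 48.600000000000001
  - 21.0
  - 12.5
  - 2.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 3.1
- - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 2.0
  - 12.5
  - 21.0
  - 48.600000000000001
  - 18.0
  - 27.5
  - 0.0
  - 0.0
  - 0.0
  - 3.1
  - 0.0
symmetry:
- spins:
  - 1
  - 2
  - 3
  group: S3
- spins:
  - 12
  - 13
  - 14
  group: S3
equivalences:
- - 1
  - 2
  - 3
  - 12
  - 13
  - 14
- - 4
  - 11
- - 5
  - 10
- - 6
  - 9
- - 15
  - 16
- - 7
  - 8
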