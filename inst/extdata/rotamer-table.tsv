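label	energy_kJmol	degeneracy	dipole_D	J_HH	J_HF
aa	0	1	NA	12.5	40
ag	2.5	1	NA	12.5	7.75
ag-	2.5	1	NA	12.5	7.75
ga	2.5	1	NA	3.275	40
gg	5	1	NA	3.275	7.75
gg-	5	1	NA	3.275	7.75
g-a	2.5	1	NA	3.275	40
g-g	5	1	NA	3.275	7.75
g-g-	5	1	NA	3.275	7.75
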