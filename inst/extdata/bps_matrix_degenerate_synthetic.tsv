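base	pos1	pos2	pos3	pos4	pos5	pos6	pos7
A	0.20	0.30	0.20	0.12	0.30	0.55	0.15
C	0.28	0.20	0.32	0.13	0.20	0.15	0.35
G	0.17	0.20	0.16	0.10	0.25	0.15	0.15
T	0.35	0.30	0.32	0.65	0.25	0.15	0.35
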