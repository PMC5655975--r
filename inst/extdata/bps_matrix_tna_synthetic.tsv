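base	pos1	pos2	pos3	pos4	pos5	pos6	pos7
A	0.10	0.40	0.15	0.00	0.45	1.00	0.10
C	0.25	0.15	0.45	0.00	0.15	0.00	0.45
G	0.10	0.15	0.10	0.00	0.20	0.00	0.10
T	0.55	0.30	0.30	1.00	0.20	0.00	0.35
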