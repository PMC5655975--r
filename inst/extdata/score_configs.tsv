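name	P1	P2	P3	Q1	Q2	Q3
score0	0	0	0	0	0	0
score1	0	1	0	0	0	0
score2	1	0	0	0	0	0
score3	0	0	1	0	0	0
score4	1	1	0	0	0	0
score5	0	1	1	0	0	0
score6	1	0	1	0	0	0
score7	1	1	1	0	0	0
score8	0	1	0	0	1	0
score9	1	0	0	1	0	0
score10	0	0	1	0	0	1
score11	1	1	0	1	1	0
score12	0	1	1	0	1	1
score13	1	0	1	1	0	1
score14	1	1	1	1	1	1
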