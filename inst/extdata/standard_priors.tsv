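name	scale	prior_mean	prior_variance	lower	upper
Te	0.004	0	0.0625	-1	0.85
Ti	0.016	0	0.0625	-1	0.85
He	8	0	0.015625	-1	0.85
Hi	32	0	0.015625	-1	0.85
G1	128	0	0.0625	-1	0.85
G2	102.4	0	0.0625	-1	0.85
G3	64	0	0.0625	-1	0.85
G4	64	0	0.0625	-1	0.85
G5	32	0	0.0625	-1	0.85
R1	0.5	0	0.0625	-1	0.85
R2	3	0	0.0625	-1	0.85
Di	0.01	0	0.03125	-1	0.85
input_gain	1	0	0.0625	-1	0.85
noise_exponent	1	0	0.015625	-1	0.85
obs_gain	1	0	0.015625	-1	0.85
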