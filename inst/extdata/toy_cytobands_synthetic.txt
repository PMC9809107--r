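chrA	0	500000	p14	gneg
chrA	500000	1000000	p13	gneg
chrA	1000000	1500000	p12	gneg
chrA	1500000	2000000	p11	gneg
chrA	2000000	2750000	q11	gneg
chrA	2750000	3500000	q12	gneg
chrA	3500000	4250000	q13	gneg
chrA	4250000	5000000	q14	gneg
chrB	0	500000	p14	gneg
chrB	500000	1000000	p13	gneg
chrB	1000000	1500000	p12	gneg
chrB	1500000	2000000	p11	gneg
chrB	2000000	2750000	q11	gneg
chrB	2750000	3500000	q12	gneg
chrB	3500000	4250000	q13	gneg
chrB	4250000	5000000	q14	gneg
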