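patient	chrom	pos	gene	cdna	protein	sample	ref_depth	alt_depth	printed_vaf_pct
GIST174	4	55593661	KIT	c.T1727C	p.L576P	FF	2	160	98.8
GIST174	4	55593661	KIT	c.T1727C	p.L576P	FFPE	12	236	95.2
GIST174	4	55593661	KIT	c.T1727C	p.L576P	PB	116	0	0
GIST165	4	55152093	PDGFRA	c.A2525T	p.D842V	FF	109	35	24.3
GIST165	4	55152093	PDGFRA	c.A2525T	p.D842V	FFPE	57	32	36.0
GIST165	4	55152093	PDGFRA	c.A2525T	p.D842V	PB	110	0	0
GIST193	5	235345	SDHA	c.C1151G	p.S384X	FF	4	50	92.6
GIST193	5	235345	SDHA	c.C1151G	p.S384X	FFPE	5	38	88.4
GIST193	5	235345	SDHA	c.C1151G	p.S384X	PB	23	24	51.1
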