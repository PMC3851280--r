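sample_id	gene	nucleotide_desc	expected_category
1	ATP13A4	g.1938A>T	VUS
1	KIAA0319	c.931G>A	VUS
2	ATP13A4	g.1938A>T	VUS
4	CNTNAP2	c.3714-7insTTG	VUS
4	ATP13A4	g.1938A>T	VUS
6	CNTNAP2	c.511C>T	LIKELY_PATHOGENIC
7	CNTNAP1	c.3191G>A	VUS_IN_GUS
8	FOXP1	c.320T>C	LIKELY_PATHOGENIC
9	KIAA0319	c.931G>A	VUS
9	SETX	g.2975A>G	VUS_IN_GUS
10	CNTNAP2	c.3714-7insTTG	VUS
10	KIAA0319	c.931G>A	VUS
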