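participant	gender	age_group	years_treatment	familial	cognitive	onset	comprehension	expression	gross_motor	oral_nonverbal
1	M	C	7+	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE
2	M	A	3	POSITIVE	NEGATIVE	POSITIVE	NEGATIVE	POSITIVE	POSITIVE	ND
3	F	C	6	ND	NEGATIVE	POSITIVE	POSITIVE	POSITIVE	ND	ND
4	M	C	6	NEGATIVE	NEGATIVE	POSITIVE	POSITIVE	POSITIVE	NEGATIVE	POSITIVE
5	F	C	7+	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE	ND
6	F	A	5	NEGATIVE	NEGATIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE
7	F	B	4	POSITIVE	NEGATIVE	ND	NEGATIVE	NEGATIVE	POSITIVE	POSITIVE
8	M	B	3	NEGATIVE	POSITIVE	POSITIVE	ND	ND	POSITIVE	POSITIVE
9	F	A	4	NEGATIVE	NEGATIVE	POSITIVE	POSITIVE	NEGATIVE	POSITIVE	POSITIVE
10	M	B	5	POSITIVE	NEGATIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE	POSITIVE
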