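gene	tier	phenotype_note	prior_variants
FOXP1	TIER_CAS	Developmental delay, expressive language deficits, ASD	NA
FOXP2	TIER_CAS	CAS (multigenerational family studies)	NA
CNTNAP2	TIER_CAS	Intellectual delay, ASD, CAS	NA
ATP13A4	TIER_CAS	ASD, CAS	p.Glu646Asp
KIAA0319	TIER_OVERLAP	Developmental dyslexia, SLI	p.Ala311Thr,c.931G>A
SETX	TIER_GUS	AOA2 (phenotype overlapping CAS)	p.Lys992Arg
CNTNAP1	TIER_GUS	No human phenotype	NA
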