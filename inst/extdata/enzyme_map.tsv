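# Synthetic metabolite -> conversion-enzyme map for the 44-analyte panel.
# Stand-in for a frozen KEGG/HMDB extraction: covers the amino-acid and
# acylcarnitine metabolism enzymes discussed for the parkinsonism case study;
# assignments are plausible but not a curated database export.
metabolite_id	enzyme_protein_id	enzyme_gene_id	role	enzyme_class
Ala	ALDH2	ALDH2	degradation	amino_acid_metabolism
Ala	AL1B1	ALDH1B1	degradation	amino_acid_metabolism
Pro	P4HA1	P4HA1	biosynthesis	amino_acid_metabolism
Pro	P4HA2	P4HA2	biosynthesis	amino_acid_metabolism
Pro	P5CR1	PYCR1	biosynthesis	amino_acid_metabolism
Pro	ALDH2	ALDH2	degradation	amino_acid_metabolism
Ile	BCAT1	BCAT1	degradation	amino_acid_metabolism
Ile	BCAT2	BCAT2	degradation	amino_acid_metabolism
Val	BCAT1	BCAT1	degradation	amino_acid_metabolism
Val	BCAT2	BCAT2	degradation	amino_acid_metabolism
Met	UD11	UGT1A1	degradation	amino_acid_metabolism
Met	AL1B1	ALDH1B1	degradation	amino_acid_metabolism
C0	CPT1A	CPT1A	biosynthesis	acylcarnitine_metabolism
C0	CPT1B	CPT1B	biosynthesis	acylcarnitine_metabolism
C0	CPT1C	CPT1C	biosynthesis	acylcarnitine_metabolism
C0	S22A6	SLC22A6	degradation	acylcarnitine_metabolism
C2	ODPA	PDHA1	biosynthesis	acylcarnitine_metabolism
C2	ODPB	PDHB	biosynthesis	acylcarnitine_metabolism
C2	FAS	FASN	degradation	acylcarnitine_metabolism
C2	S22A6	SLC22A6	degradation	acylcarnitine_metabolism
C3	ACC1	ACACA	biosynthesis	acylcarnitine_metabolism
C4	CPT1B	CPT1B	biosynthesis	acylcarnitine_metabolism
C5	CPT1B	CPT1B	biosynthesis	acylcarnitine_metabolism
C6	OCTC	CROT	degradation	acylcarnitine_metabolism
C8	OCTC	CROT	degradation	acylcarnitine_metabolism
C8	CPT1A	CPT1A	biosynthesis	acylcarnitine_metabolism
C10	OCTC	CROT	degradation	acylcarnitine_metabolism
C10:1	OCTC	CROT	degradation	acylcarnitine_metabolism
C12	CPT1A	CPT1A	biosynthesis	acylcarnitine_metabolism
C14	CPT1A	CPT1A	biosynthesis	acylcarnitine_metabolism
C14:1	CPT1B	CPT1B	biosynthesis	acylcarnitine_metabolism
C16	FAS	FASN	biosynthesis	acylcarnitine_metabolism
C16	CPT1A	CPT1A	biosynthesis	acylcarnitine_metabolism
C16	FURIN	FURIN	degradation	acylcarnitine_metabolism
C16:1	CPT1B	CPT1B	biosynthesis	acylcarnitine_metabolism
C18	CPT1A	CPT1A	biosynthesis	acylcarnitine_metabolism
C18	FURIN	FURIN	degradation	acylcarnitine_metabolism
C18:1	CPT1C	CPT1C	biosynthesis	acylcarnitine_metabolism
C18:2	CPT1C	CPT1C	biosynthesis	acylcarnitine_metabolism
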