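pathway_id	gene_name
UREA_CYCLE	argA
UREA_CYCLE	argB
UREA_CYCLE	argC
UREA_CYCLE	argD
UREA_CYCLE	argE
UREA_CYCLE	argF
UREA_CYCLE	argG
UREA_CYCLE	argH
UREA_CYCLE	gdhA
UREA_CYCLE	gltB
UREA_CYCLE	ureC
FATTY_ACID_BIOSYNTHESIS	fabA
FATTY_ACID_BIOSYNTHESIS	fabB
FATTY_ACID_BIOSYNTHESIS	fabD
FATTY_ACID_BIOSYNTHESIS	fabF
FATTY_ACID_BIOSYNTHESIS	fabG
FATTY_ACID_BIOSYNTHESIS	fabH
FATTY_ACID_BIOSYNTHESIS	fabI
FATTY_ACID_BIOSYNTHESIS	fabZ
FATTY_ACID_BIOSYNTHESIS	accA
FATTY_ACID_BIOSYNTHESIS	accB
FATTY_ACID_BIOSYNTHESIS	accC
FATTY_ACID_BIOSYNTHESIS	accD
TCA_CYCLE	sucA
TCA_CYCLE	sucB
TCA_CYCLE	sdhA
TCA_CYCLE	mdh
TCA_CYCLE	gltA
TCA_CYCLE	icd
TCA_CYCLE	fumA
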