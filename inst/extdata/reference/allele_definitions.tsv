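gene	star_allele	rsid_list	activity_value	function_class
CYP2C19	*1		NA	normal
CYP2C19	*2	rs4244285=A	NA	no
CYP2C19	*3	rs4986893=A	NA	no
CYP2C19	*17	rs12248560=T	NA	increased
CYP2D6	*1		1	normal
CYP2D6	*2	rs16947=A	1	normal
CYP2D6	*3	rs35742686=del	0	no
CYP2D6	*4	rs3892097=A	0	no
CYP2D6	*6	rs5030655=del	0	no
CYP2D6	*10	rs1065852=T	0.25	decreased
CYP2D6	*17	rs28371706=T	0.5	decreased
CYP2D6	*41	rs28371725=T	0.5	decreased
CYP2C9	*1		1	normal
CYP2C9	*2	rs1799853=T	0.5	decreased
CYP2C9	*3	rs1057910=C	0	no
CYP3A5	*1		NA	normal
CYP3A5	*3	rs776746=G	NA	no
CYP3A5	*6	rs10264272=T	NA	no
CYP3A5	*7	rs41303343=ins	NA	no
SLCO1B1	*1		NA	normal
SLCO1B1	*5	rs4149056=C	NA	decreased
CYP4F2	*1		NA	normal
CYP4F2	*3	rs2108622=T	NA	decreased
VKORC1	G		NA	normal
VKORC1	A	rs9923231=A	NA	decreased
CYP2C-cluster	G		NA	normal
CYP2C-cluster	A	rs12777823=A	NA	unknown
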