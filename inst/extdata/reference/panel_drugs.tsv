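drug	gene	actionable_phenotypes	future_watch_phenotypes	evidence_grade	eligible_routes	synonyms
celecoxib	CYP2C9	PM;IM		moderate	oral	celebrex
ibuprofen	CYP2C9	PM;IM		moderate	oral	advil;motrin
flurbiprofen	CYP2C9	PM;IM		moderate	oral	
meloxicam	CYP2C9	PM;IM		moderate	oral	mobic
piroxicam	CYP2C9	PM;IM		moderate	oral	feldene
codeine	CYP2D6	PM;IM;UM		strong	oral	
hydrocodone	CYP2D6	PM;UM		optional	oral	hysingla;zohydro
tramadol	CYP2D6	PM;IM;UM		strong	oral	ultram
atomoxetine	CYP2D6	PM;UM		moderate	oral	strattera
fluvoxamine	CYP2D6	PM		optional	oral	luvox
paroxetine	CYP2D6	PM;UM		moderate	oral	paxil
citalopram	CYP2C19	PM;UM		moderate	oral	celexa
escitalopram	CYP2C19	PM;UM		moderate	oral	lexapro
sertraline	CYP2C19	PM;UM		optional	oral	zoloft
omeprazole	CYP2C19	PM;IM;UM	NM;RM	moderate	oral	prilosec
pantoprazole	CYP2C19	PM;IM;UM	NM;RM	moderate	oral	protonix
rabeprazole	CYP2C19	PM;IM;UM	NM;RM	optional	oral	aciphex
lansoprazole	CYP2C19	PM;IM;UM	NM;RM	moderate	oral	prevacid
dexlansoprazole	CYP2C19	PM;IM;UM	NM;RM	optional	oral	dexilant
esomeprazole	CYP2C19	PM;IM;UM	NM;RM	optional	oral	nexium
clopidogrel	CYP2C19	PM;IM		strong	oral	plavix
voriconazole	CYP2C19	PM;RM;UM		strong	oral	vfend
tacrolimus	CYP3A5	NM		strong	oral	prograf
warfarin	CYP2C9	PM;IM		strong	oral	coumadin;jantoven
warfarin	VKORC1	G/A;A/A		strong	oral	coumadin;jantoven
simvastatin	SLCO1B1	decreased function;poor function		strong	oral	zocor
amitriptyline	CYP2D6	PM;IM;UM		strong	oral	elavil
amitriptyline	CYP2C19	PM;UM		optional	oral	elavil
nortriptyline	CYP2D6	PM;IM;UM		strong	oral	pamelor
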