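drug	class
omeprazole	PPI
pantoprazole	PPI
rabeprazole	PPI
lansoprazole	PPI
dexlansoprazole	PPI
esomeprazole	PPI
citalopram	SSRI
escitalopram	SSRI
sertraline	SSRI
paroxetine	SSRI
fluvoxamine	SSRI
codeine	opioid
hydrocodone	opioid
tramadol	opioid
celecoxib	NSAID
ibuprofen	NSAID
flurbiprofen	NSAID
meloxicam	NSAID
piroxicam	NSAID
atomoxetine	other
clopidogrel	other
voriconazole	other
tacrolimus	other
warfarin	other
simvastatin	other
amitriptyline	other
nortriptyline	other
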