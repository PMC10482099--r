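drug	gene	strength
bupropion	CYP2D6	strong
fluoxetine	CYP2D6	strong
paroxetine	CYP2D6	strong
quinidine	CYP2D6	strong
terbinafine	CYP2D6	strong
abiraterone	CYP2D6	moderate
cinacalcet	CYP2D6	moderate
duloxetine	CYP2D6	moderate
mirabegron	CYP2D6	moderate
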