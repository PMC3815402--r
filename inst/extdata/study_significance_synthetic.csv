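predictor,study_id
age,alboni
age,calkins
age,iglesias
age,sud
gender,alboni
gender,calkins
gender,iglesias
structural_heart_disease,delrosso02
structural_heart_disease,sud
structural_heart_disease,iglesias
spells,calkins
spells,delrosso02
spells,sud
nausea,alboni
nausea,delrosso02
nausea,iglesias
diaphoresis,alboni
diaphoresis,delrosso02
diaphoresis,iglesias
prodrome,alboni
prodrome,delrosso08
prodrome,iglesias
blurred_vision,alboni
blurred_vision,delrosso02
blurred_vision,iglesias
palpitations,alboni
palpitations,calkins
palpitations,delrosso08
supine_syncope,alboni
supine_syncope,calkins
supine_syncope,delrosso08
effort_syncope,alboni
effort_syncope,delrosso08
effort_syncope,galizia
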