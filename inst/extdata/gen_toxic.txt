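# Generator lexicon: TOXIC (toxic effects)
apoptosis
necrosis
inflammation
cytotoxicity
genotoxicity
fibrosis
granulomas
detachment
death
edema
lesions
hemolysis
carcinogenicity
neurotoxicity
immunotoxicity
vacuolization
degeneration
thrombosis
teratogenicity
hepatotoxicity
oxidative stress
DNA damage
cell death
membrane disruption
lipid peroxidation
chromosomal aberrations
growth inhibition
mitochondrial dysfunction
reproductive impairment
pulmonary fibrosis
oxidative DNA damage
acute phase response
reactive oxygen generation
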