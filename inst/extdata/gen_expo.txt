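# Generator lexicon: EXPO (routes of exposure)
inhalation
ingestion
instillation
injection
pulverization
gavage
immersion
inoculation
insufflation
implantation
nebulization
aspiration
dermal contact
oral administration
intravenous injection
intratracheal instillation
dietary intake
ocular instillation
subcutaneous injection
intraperitoneal injection
dermal application
airborne release
whole body inhalation
repeated dermal application
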