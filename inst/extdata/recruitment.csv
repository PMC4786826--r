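key,value
twin_pairs_identified,221
pairs_presumed_concordant,146
pairs_presumed_discordant,75
individuals_approached,442
individuals_responded,372
complete_pairs_presumed_concordant_after_survey,117
complete_pairs_presumed_discordant_after_survey,48
pairs_enrolled_concordant,5
pairs_enrolled_discordant,5
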