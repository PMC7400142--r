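id,name,impact
social_contacts,Social contacts,0.78
housing,Housing,0.77
health_care,Health care,0.77
social_care,Social care,0.75
daily_activities,Daily activities,0.72
residence_security,Residence security,0.70
access_education,Access to education,0.67
income_security,Income security,0.65
sociocultural_adaptation,Sociocultural adaptation,0.58
political_climate,Political and social climate,0.53
german_language,German language skills,0.52
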