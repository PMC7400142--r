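source,target,weight,category_attested
political_climate,social_contacts,6.5,yes
german_language,social_contacts,6.5,yes
sociocultural_adaptation,social_contacts,6.0,no
daily_activities,social_contacts,5.5,yes
social_care,social_contacts,6.0,no
access_education,social_contacts,6.0,no
social_contacts,sociocultural_adaptation,6.0,no
social_contacts,german_language,6.5,yes
sociocultural_adaptation,german_language,7.5,yes
german_language,sociocultural_adaptation,6.5,yes
german_language,access_education,6.5,yes
access_education,german_language,6.5,yes
german_language,income_security,6.0,no
access_education,daily_activities,6.0,no
income_security,housing,6.0,no
income_security,daily_activities,6.0,no
income_security,health_care,6.0,no
residence_security,income_security,6.5,yes
access_education,income_security,6.0,no
residence_security,housing,5.5,yes
residence_security,access_education,5.5,yes
political_climate,residence_security,6.0,no
political_climate,social_care,6.0,no
social_contacts,daily_activities,6.0,no
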