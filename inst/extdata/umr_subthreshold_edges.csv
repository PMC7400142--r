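source,target,note
german_language,health_care,reported to exist below the display threshold; weight unpublished
residence_security,social_care,reported to exist below the display threshold; weight unpublished
housing,daily_activities,reported to exist below the display threshold; weight unpublished
access_education,sociocultural_adaptation,reciprocal sub-threshold relation; weight unpublished
sociocultural_adaptation,access_education,reciprocal sub-threshold relation; weight unpublished
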