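# Comorbidity and injury ICD-10 code sets, one per line:
#   name: CODES [| settings]
# CODES is a comma-separated list of prefixes (F06) and/or three-character
# ranges (S00-S09); settings is "any" (default) or "inpatient_primary".
depression: F32-F33
organic_mental: F06
somatoform: F45
personality: F07
gastrointestinal: K20-K93
vascular: I60-I79, G45
hypertension: I10-I15
head_injury: S00-S09
trunk_limb_injury: T08-T14
knee_lower_leg_injury: S80-S89
ankle_foot_injury: S90-S99
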