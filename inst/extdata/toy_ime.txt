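Acute kidney injury
Seizure
Suicidal ideation
Gastrointestinal haemorrhage
Hepatitis
Immune reconstitution inflammatory syndrome
Foetal cardiac disorder
Neural tube defect
Abortion spontaneous
Foetal growth restriction
Jaundice
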