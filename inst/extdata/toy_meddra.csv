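pt,soc
Renal failure,Renal and urinary disorders
Acute kidney injury,Renal and urinary disorders
Renal impairment,Renal and urinary disorders
Nephrolithiasis,Renal and urinary disorders
Proteinuria,Renal and urinary disorders
Drug-induced liver injury,Hepatobiliary disorders
Hepatic necrosis,Hepatobiliary disorders
Acute hepatic failure,Hepatobiliary disorders
Hepatitis,Hepatobiliary disorders
Jaundice,Hepatobiliary disorders
Hepatomegaly,Hepatobiliary disorders
Hyperbilirubinaemia,Hepatobiliary disorders
Pancreatitis,Gastrointestinal disorders
Pancreatitis acute,Gastrointestinal disorders
Nausea,Gastrointestinal disorders
Vomiting,Gastrointestinal disorders
Diarrhoea,Gastrointestinal disorders
Abdominal pain,Gastrointestinal disorders
Gastrointestinal haemorrhage,Gastrointestinal disorders
Progressive multifocal leukoencephalopathy,Nervous system disorders
Headache,Nervous system disorders
Dizziness,Nervous system disorders
Seizure,Nervous system disorders
Tremor,Nervous system disorders
Somnolence,Nervous system disorders
Immune reconstitution inflammatory syndrome,Nervous system disorders
Deafness neurosensory,Ear and labyrinth disorders
Tinnitus,Ear and labyrinth disorders
Vertigo,Ear and labyrinth disorders
Insomnia,Psychiatric disorders
Depression,Psychiatric disorders
Anxiety,Psychiatric disorders
Suicidal ideation,Psychiatric disorders
Abnormal dreams,Psychiatric disorders
Rhabdomyolysis,Musculoskeletal and connective tissue disorders
Myalgia,Musculoskeletal and connective tissue disorders
Arthralgia,Musculoskeletal and connective tissue disorders
Dermatitis exfoliative generalised,Skin and subcutaneous tissue disorders
Rash,Skin and subcutaneous tissue disorders
Pruritus,Skin and subcutaneous tissue disorders
Stevens-Johnson syndrome,Skin and subcutaneous tissue disorders
Anencephaly,"Congenital, familial and genetic disorders"
Spina bifida,"Congenital, familial and genetic disorders"
Gastroschisis,"Congenital, familial and genetic disorders"
Foetal cardiac disorder,"Congenital, familial and genetic disorders"
Neural tube defect,"Congenital, familial and genetic disorders"
Abortion spontaneous,"Pregnancy, puerperium and perinatal conditions"
Premature baby,"Pregnancy, puerperium and perinatal conditions"
Neonatal death,"Pregnancy, puerperium and perinatal conditions"
Foetal growth restriction,"Pregnancy, puerperium and perinatal conditions"
Weight increased,Investigations
Blood glucose increased,Investigations
Hyperlipidaemia,Metabolism and nutrition disorders
Hyperglycaemia,Metabolism and nutrition disorders
Fatigue,General disorders and administration site conditions
Pyrexia,General disorders and administration site conditions
Drug ineffective,General disorders and administration site conditions
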