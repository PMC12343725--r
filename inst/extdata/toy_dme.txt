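Renal failure
Drug-induced liver injury
Hepatic necrosis
Acute hepatic failure
Pancreatitis
Pancreatitis acute
Progressive multifocal leukoencephalopathy
Deafness neurosensory
Rhabdomyolysis
Dermatitis exfoliative generalised
Stevens-Johnson syndrome
Anencephaly
Spina bifida
Gastroschisis
Neonatal death
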