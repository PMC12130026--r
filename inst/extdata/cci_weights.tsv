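condition_code	item	weight
myocardial_infarction	mi	1
heart_failure	chf	1
heart_failure_nyha34	chf	1
heart_failure_preserved_ef	chf	1
peripheral_vascular_disease	pvd	1
cerebrovascular_disease	cvd	1
stroke	cvd	1
dementia	dementia	1
lewy_body_dementia	dementia	1
copd	copd	1
rheumatoid_arthritis	ctd	1
peptic_ulcer	pud	1
chronic_liver_disease	liver_mild	1
liver_failure	liver_severe	3
diabetes_t2	dm	1
diabetes_end_organ	dm_end_organ	2
hemiplegia	hemiplegia	2
renal_failure	renal	2
cancer	malignancy	2
breast_cancer	malignancy	2
metastatic_tumor	mets	6
aids	aids	6
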