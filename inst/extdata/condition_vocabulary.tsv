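code	label	chronic
hypertension	Hypertension	1
uncontrolled_hypertension	Uncontrolled severe hypertension	1
severe_aortic_stenosis	Severe symptomatic aortic stenosis	0
heart_failure	Heart failure	1
heart_failure_nyha34	Heart failure NYHA class III or IV	1
heart_failure_preserved_ef	Heart failure with preserved systolic function	1
atrial_fibrillation	Chronic atrial fibrillation	1
svt	Supraventricular tachyarrhythmia	0
bradycardia	Persistent bradycardia (below 50-60/min)	0
heart_block	Type II or complete heart block	0
angina	Angina pectoris	1
coronary_artery_disease	Coronary artery disease	1
myocardial_infarction	Myocardial infarction	1
acute_coronary_syndrome	Current acute coronary syndrome	0
aortic_aneurysm	Aortic aneurysm	0
peripheral_vascular_disease	Peripheral vascular disease	1
cerebrovascular_disease	Cerebrovascular disease	1
stroke	Stroke or TIA history	1
carotid_stenosis	High-grade symptomatic carotid stenosis	0
coronary_stent_recent	Coronary stent inserted within previous 12 months	0
coronary_stenosis_high_grade	Angiographically proven coronary stenosis above 50 percent	0
metallic_heart_valve	Metallic heart valve in situ	0
mitral_stenosis	Moderate to severe mitral stenosis	0
primary_cv_prevention	Primary cardiovascular prevention context (no established CVD)	0
orthostatic_hypotension	Persistent orthostatic (postural) hypotension	0
symptomatic_hypotension	Symptomatic hypotension	0
syncope	Recurrent unexplained syncope	0
recurrent_falls	Recurrent falls	0
bleeding_diathesis	Bleeding diathesis	0
recent_spontaneous_bleeding	Recent non-trivial spontaneous bleeding	0
recent_bleeding	Current or recent significant bleeding	0
major_hemorrhage_history	Previous major haemorrhage	0
gi_bleed_history	Upper gastrointestinal bleeding history	0
gave	Gastric antral vascular ectasia	0
peptic_ulcer	Peptic ulcer disease	0
erosive_esophagitis	Erosive peptic esophagitis	0
gastritis	Gastritis or duodenitis	0
dysphagia	Dysphagia	0
chronic_constipation	Chronic constipation	0
chronic_liver_disease	Chronic liver disease	0
liver_failure	Severe liver disease or liver failure	0
nephrotic_syndrome	Nephrotic syndrome	0
renal_failure	Renal failure	0
dvt_history	First deep venous thrombosis	0
pe_history	First pulmonary embolus	0
thrombosis_risk_persistent	Continuing provoking risk factor for venous thromboembolism	0
dementia	Dementia	0
lewy_body_dementia	Dementia with Lewy bodies	0
chronic_cognitive_impairment	Chronic cognitive impairment	0
delirium	Delirium	0
parkinsonism	Parkinsonism	0
drug_induced_parkinsonism	Drug-induced parkinsonism	0
essential_tremor	Benign essential tremor	0
epilepsy	Epilepsy	0
seizure_history	Previous seizure disorder	0
depression	Major depression	0
psychosis	Psychosis	0
narrow_angle_glaucoma	Narrow-angle glaucoma	0
bph_luts	Lower urinary tract symptoms with benign prostatic hyperplasia	0
urinary_retention_history	Prior urinary retention	0
high_post_void_residual	Post-void residual volume above 200 mL	0
urinary_incontinence	Urinary incontinence	0
urge_incontinence	Urinary urgency or urge incontinence	0
overactive_bladder	Overactive bladder	0
asymptomatic_bacteriuria	Asymptomatic bacteriuria	0
gout	Gout	0
osteoarthritis	Osteoarthritis	0
rheumatoid_arthritis	Rheumatoid arthritis	0
diabetes_t2	Type 2 diabetes mellitus	1
diabetes_end_organ	Diabetes with end-organ damage	1
frequent_hypoglycemia	Frequent hypoglycaemic episodes	0
breast_cancer	Breast cancer history	1
intact_uterus	Intact uterus	0
cancer	Malignancy (non-metastatic)	1
metastatic_tumor	Metastatic solid tumour	1
hemiplegia	Hemiplegia	0
aids	AIDS	0
copd	Chronic obstructive pulmonary disease	0
respiratory_failure	Acute or chronic respiratory failure	0
allergy	Allergy	0
pruritus	Pruritus	0
frailty_limited_life_expectancy	Established frailty with life expectancy under 3 years	0
antihypertensive_intolerance	Documented intolerance or failure of other antihypertensive classes	0
xoi_contraindication	Contraindication to xanthine-oxidase inhibitors	0
none	Explicitly no evidence-based indication recorded	0
anxiety	Anxiety	0
insomnia	Insomnia	0
agitation	Agitated behaviour	0
bpsd	Behavioural and psychological symptoms of dementia	0
ncsd	Non-cognitive symptoms of dementia	0
eps	Extrapyramidal side effects of antipsychotics	0
nausea	Nausea or vomiting	0
hiccups	Persistent hiccups	0
tremor	Tremor	0
mild_pain	Mild pain	0
moderate_pain	Moderate pain	0
severe_pain	Severe pain	0
pain	Pain (unspecified)	0
non_neuropathic_pain	Non-neuropathic pain	0
neuropathic_pain	Neuropathic pain	0
low_back_pain	Low back pain	0
ankle_edema	Dependent ankle oedema	0
stroke_prevention	Stroke prevention context	0
gout_prophylaxis	Prophylaxis of gout relapse	0
urinary_frequency	Urinary frequency	0
hormone_replacement	Menopausal hormone therapy context	0
appetite_stimulation	Appetite stimulation	0
infection	Acute infection	0
osteoporosis	Osteoporosis	0
anemia	Anaemia	0
hypothyroidism	Hypothyroidism	0
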