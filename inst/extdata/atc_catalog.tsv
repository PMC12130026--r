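code	name	tags
B01AC06	Acetylsalicylic acid	aspirin;antiplatelet
B01AC04	Clopidogrel	antiplatelet
B01AC05	Ticlopidine	antiplatelet;ticlopidine
B01AC24	Ticagrelor	antiplatelet;pgp_inhibitor
B01AA03	Warfarin	vka
B01AB05	Enoxaparin	heparin
B01AF01	Rivaroxaban	fxa
B01AF02	Apixaban	fxa
B01AE07	Dabigatran etexilate	dti
C03CA01	Furosemide	loop_diuretic;antihypertensive
C03CA04	Torasemide	loop_diuretic;antihypertensive
C03AA03	Hydrochlorothiazide	thiazide;antihypertensive
C03DA01	Spironolactone	aldosterone_antagonist;potassium_sparing;antihypertensive
C03DB02	Triamterene	potassium_sparing
C09AA02	Enalapril	ace_inhibitor;antihypertensive
C09AA03	Lisinopril	ace_inhibitor;antihypertensive
C09CA01	Losartan	arb;antihypertensive
C07AB02	Metoprolol	beta_blocker;antihypertensive
C07AB03	Atenolol	beta_blocker;antihypertensive
C07AB07	Bisoprolol	beta_blocker;antihypertensive
C07AA05	Propranolol	beta_blocker;beta_blocker_nonselective;antihypertensive
C07AG02	Carvedilol	beta_blocker;beta_blocker_nonselective;antihypertensive;pgp_inhibitor
C08DA01	Verapamil	verapamil_diltiazem;antihypertensive;pgp_inhibitor;constipating
C08DB01	Diltiazem	verapamil_diltiazem;antihypertensive
C08CA01	Amlodipine	ccb_dihydropyridine;antihypertensive
C01AA05	Digoxin	digoxin;qtc_prolonging
C01BD01	Amiodarone	amiodarone;qtc_prolonging;pgp_inhibitor
C01BD07	Dronedarone	qtc_prolonging;pgp_inhibitor
C01DA02	Glyceryl trinitrate	nitrate;vasodilator
C01DA14	Isosorbide mononitrate	nitrate;vasodilator
C02DB02	Hydralazine	vasodilator;antihypertensive
C02AB01	Methyldopa	centrally_acting_antihypertensive;antihypertensive
C02AC01	Clonidine	centrally_acting_antihypertensive;antihypertensive
C02CA04	Doxazosin	alpha1_blocker;antihypertensive
G04CA01	Alfuzosin	alpha1_blocker
G04CA02	Tamsulosin	alpha1_blocker
G04CA04	Silodosin	alpha1_blocker;silodosin_exempt
G04BE03	Sildenafil	pde5_inhibitor;vasodilator
C10AA01	Simvastatin	statin
C10AA05	Atorvastatin	statin
H02AB04	Methylprednisolone	corticosteroid_systemic
H02AB06	Prednisolone	corticosteroid_systemic
H02AB09	Hydrocortisone	corticosteroid_systemic
R03BA02	Budesonide	corticosteroid_inhaled;respiratory_maintenance
R03BB04	Tiotropium bromide	lama;respiratory_maintenance
R03AC02	Salbutamol	respiratory_maintenance
R03DA04	Theophylline	theophylline
A02BC01	Omeprazole	ppi
A02BC02	Pantoprazole	ppi
A02BA03	Famotidine	h2_antagonist
A02AB01	Aluminium hydroxide	constipating
B03AA07	Ferrous sulfate	oral_iron;constipating
A03FA01	Metoclopramide	metoclopramide_prochlorperazine
N05AB04	Prochlorperazine	metoclopramide_prochlorperazine;phenothiazine;antipsychotic
A10BB01	Glibenclamide	sulfonylurea;sulfonylurea_long_acting
A10BB09	Gliclazide	sulfonylurea
A10BB12	Glimepiride	sulfonylurea;sulfonylurea_long_acting
A10BG03	Pioglitazone	thiazolidinedione
A10BK01	Dapagliflozin	sglt2
A10BK03	Empagliflozin	sglt2
A10BA02	Metformin	metformin
A10AB01	Insulin (human)	
G03CA03	Estradiol	estrogen_systemic
G03DA04	Progesterone	progestogen
L02AB01	Megestrol	megestrol;progestogen
H03AA01	Levothyroxine sodium	levothyroxine
H01BA02	Desmopressin	vasopressin_analog
G04BD04	Oxybutynin	antimuscarinic_urological;anticholinergic
G04BD07	Tolterodine	antimuscarinic_urological;anticholinergic
G04BD12	Mirabegron	mirabegron;qtc_prolonging
N06DA02	Donepezil	ache_inhibitor
N06DX01	Memantine	memantine
N06BX03	Piracetam	nootropic
N06DX02	Ginkgo folium	nootropic
N06BA07	Modafinil	nootropic
N04BA02	Levodopa and decarboxylase inhibitor	levodopa_dopamine_agonist
N04BC05	Pramipexole	levodopa_dopamine_agonist
N04AA02	Biperiden	antiparkinson_anticholinergic;anticholinergic
N04AA04	Procyclidine	antiparkinson_anticholinergic;anticholinergic
N03AF01	Carbamazepine	antiepileptic
N03AG01	Valproic acid	antiepileptic
N03AX14	Levetiracetam	antiepileptic
N03AX12	Gabapentin	gabapentinoid;antiepileptic
N03AX16	Pregabalin	gabapentinoid;antiepileptic
N03AE01	Clonazepam	benzodiazepine;antiepileptic
M05BA04	Alendronic acid	bisphosphonate
M04AC01	Colchicine	colchicine
M04AA01	Allopurinol	xo_inhibitor
J01XE01	Nitrofurantoin	antibiotic;nitrofurantoin
L04AX03	Methotrexate	methotrexate
J01MA02	Ciprofloxacin	antibiotic;qtc_prolonging
J01CA04	Amoxicillin	antibiotic
J01DD04	Ceftriaxone	antibiotic
J01FA09	Clarithromycin	antibiotic;qtc_prolonging;pgp_inhibitor
J02AB02	Ketoconazole	pgp_inhibitor
D04AA16	Pheniramine	antihistamine_first_gen;anticholinergic
R06AB04	Chlorphenamine	antihistamine_first_gen;anticholinergic
R06AD02	Promethazine	antihistamine_first_gen;anticholinergic;phenothiazine
R06AA02	Diphenhydramine	antihistamine_first_gen;anticholinergic
R06AE07	Cetirizine	
N06AA09	Amitriptyline	tca;antidepressant;anticholinergic;qtc_prolonging
N06AB03	Fluoxetine	ssri;antidepressant
N06AB04	Citalopram	ssri;antidepressant;qtc_dose_conditional
N06AB06	Sertraline	ssri;antidepressant
N06AB10	Escitalopram	ssri;antidepressant;qtc_dose_conditional
N06AX16	Venlafaxine	snri;antidepressant
N06AX21	Duloxetine	snri;antidepressant
N05BA01	Diazepam	benzodiazepine
N05BA06	Lorazepam	benzodiazepine
N05CF01	Zopiclone	z_drug
N05CF02	Zolpidem	z_drug
N05AD01	Haloperidol	antipsychotic;qtc_prolonging
N05AX08	Risperidone	antipsychotic
N05AH02	Clozapine	antipsychotic;antipsychotic_antimuscarinic;anticholinergic
N05AH03	Olanzapine	antipsychotic;antipsychotic_antimuscarinic;anticholinergic
N05AH04	Quetiapine	antipsychotic
N05AA01	Chlorpromazine	antipsychotic;phenothiazine;antipsychotic_antimuscarinic;anticholinergic;qtc_prolonging
N05AN01	Lithium	lithium;qtc_prolonging
A04AA01	Ondansetron	qtc_prolonging
M03BX02	Tizanidine	qtc_prolonging
N02AA01	Morphine	opioid;opioid_strong;opioid_short_acting;constipating
N02AA05	Oxycodone	opioid;opioid_strong;opioid_long_acting;constipating
N02AB02	Pethidine	opioid;opioid_strong;opioid_short_acting;constipating
N02AB03	Fentanyl	opioid;opioid_strong;opioid_long_acting;constipating
N02AE01	Buprenorphine	opioid;opioid_strong;opioid_long_acting;constipating
N02AX02	Tramadol	opioid;opioid_strong;opioid_short_acting;constipating
N02BE01	Paracetamol	paracetamol
N01BB02	Lidocaine	lidocaine_patch
M01AB05	Diclofenac	nsaid
M01AE01	Ibuprofen	nsaid
M01AE02	Naproxen	nsaid
M01AH01	Celecoxib	nsaid;cox2_selective
A06AD11	Lactulose	laxative
A06AB02	Bisacodyl	laxative
A06AB06	Senna glycosides	laxative
A11GA01	Ascorbic acid	
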