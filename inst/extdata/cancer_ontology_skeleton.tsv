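concept_id	parent_id	preferred_label	term_type	surface_form
cancer_type		cancer type	preferred	cancer type
cancer_type		cancer type	synonym	cancer
cancer_type		cancer type	synonym	am
cancer_type		cancer type	synonym	agseong
colon_cancer	cancer_type	colon cancer	preferred	colon cancer
colon_cancer	cancer_type	colon cancer	synonym	daejang-am
breast_cancer	cancer_type	breast cancer	preferred	breast cancer
breast_cancer	cancer_type	breast cancer	synonym	yubang-am
stomach_cancer	cancer_type	stomach cancer	preferred	stomach cancer
stomach_cancer	cancer_type	stomach cancer	synonym	wi-am
cervical_cancer	cancer_type	cervical cancer	preferred	cervical cancer
cervical_cancer	cancer_type	cervical cancer	synonym	jagyeongbu-am
lung_cancer	cancer_type	lung cancer	preferred	lung cancer
lung_cancer	cancer_type	lung cancer	synonym	pye-am
liver_cancer	cancer_type	liver cancer	preferred	liver cancer
liver_cancer	cancer_type	liver cancer	synonym	gan-am
pancreatic_cancer	cancer_type	pancreatic cancer	preferred	pancreatic cancer
pancreatic_cancer	cancer_type	pancreatic cancer	synonym	chwejang-am
prostate_cancer	cancer_type	prostate cancer	preferred	prostate cancer
prostate_cancer	cancer_type	prostate cancer	synonym	jeonripseon-am
brain_tumor	cancer_type	brain tumor	preferred	brain tumor
brain_tumor	cancer_type	brain tumor	synonym	noejongyang
leukemia	cancer_type	leukemia	preferred	leukemia
leukemia	cancer_type	leukemia	synonym	baekhyeolbyeong
thyroid_cancer	cancer_type	thyroid cancer	preferred	thyroid cancer
thyroid_cancer	cancer_type	thyroid cancer	synonym	gapsangseon-am
prevention		prevention	preferred	prevention
prevention		prevention	synonym	yebang
diagnosis		diagnosis	preferred	diagnosis
diagnosis		diagnosis	synonym	jindan
diagnosis		diagnosis	synonym	jaegeomsa
diagnosis		diagnosis	abbreviation	jaegeom
diagnosis		diagnosis	synonym	cho-eumpa
diagnosis		diagnosis	abbreviation	chompa
treatment		treatment	preferred	treatment
treatment		treatment	synonym	chiryo
treatment		treatment	synonym	holeumon
treatment		treatment	abbreviation	holmon
unspecified_treatment	treatment	unspecified treatment	preferred	unspecified treatment
surgery	treatment	surgery	preferred	surgery
surgery	treatment	surgery	synonym	susul
chemotherapy	treatment	chemotherapy	preferred	chemotherapy
chemotherapy	treatment	chemotherapy	synonym	hangam-chiryo
prognosis		prognosis	preferred	prognosis
prognosis		prognosis	synonym	yehu
recurrence	prognosis	recurrence	preferred	recurrence
recurrence	prognosis	recurrence	synonym	jaebal
cure	prognosis	cure	preferred	cure
cure	prognosis	cure	synonym	wanchi
cure	prognosis	cure	heteronym	jol-eob
risk_factor		risk factor	preferred	risk factor
health_condition_risk	risk_factor	health condition risk factor	preferred	health condition risk factor
health_condition_risk	risk_factor	health condition risk factor	synonym	related disease
demographic_risk	risk_factor	demographic risk factor	preferred	demographic risk factor
lifestyle_risk	risk_factor	lifestyle risk factor	preferred	lifestyle risk factor
environmental_risk	risk_factor	environmental risk factor	preferred	environmental risk factor
hereditary_risk	risk_factor	hereditary risk factor	preferred	hereditary risk factor
gender	demographic_risk	gender	preferred	gender
gender	demographic_risk	gender	synonym	seongbyeol
age	demographic_risk	age	preferred	age
age	demographic_risk	age	synonym	yeonryeong
dietary_risk	lifestyle_risk	dietary risk factor	preferred	dietary risk factor
obesity	lifestyle_risk	obesity	preferred	obesity
obesity	lifestyle_risk	obesity	synonym	bi-man
tobacco	lifestyle_risk	tobacco	preferred	tobacco
tobacco	lifestyle_risk	tobacco	synonym	smoking
tobacco	lifestyle_risk	tobacco	synonym	dambae
chemical_risk	environmental_risk	chemical risk factor	preferred	chemical risk factor
infectious_agent	environmental_risk	infectious agent	preferred	infectious agent
infectious_agent	environmental_risk	infectious agent	synonym	gamyeom
symptom		symptom	preferred	symptom
symptom		symptom	synonym	jeungsang
digestive_symptom	symptom	digestive symptom	preferred	digestive symptom
psychological_symptom	symptom	psychological symptom	preferred	psychological symptom
neurological_symptom	symptom	neurological symptom	preferred	neurological symptom
metabolic_symptom	symptom	metabolic symptom	preferred	metabolic symptom
sexual_reproductive_symptom	symptom	sexual and reproductive symptom	preferred	sexual and reproductive symptom
dealing_with_cancer		dealing with cancer	preferred	dealing with cancer
daily_life	dealing_with_cancer	daily life	preferred	daily life
leisure	dealing_with_cancer	leisure	preferred	leisure
support_group	dealing_with_cancer	support group	preferred	support group
support_group	dealing_with_cancer	support group	synonym	support community
diet	daily_life	diet	preferred	diet
diet	daily_life	diet	synonym	food
diet	daily_life	diet	synonym	protein
diet	daily_life	diet	synonym	fruit
diet	daily_life	diet	synonym	vitamin
diet	daily_life	diet	synonym	meal
diet	daily_life	diet	synonym	vegetable
diet	daily_life	diet	synonym	nutrition
exercise	daily_life	exercise	preferred	exercise
exercise	daily_life	exercise	synonym	undong
sex_life	leisure	sex life	preferred	sex life
travel	leisure	travel	preferred	travel
travel	leisure	travel	synonym	yeohaeng
driving	leisure	driving	preferred	driving
driving	leisure	driving	synonym	unjeon
emotion		emotion	preferred	emotion
emotion		emotion	synonym	gamjeong
overwhelmed	emotion	overwhelmed	preferred	overwhelmed
denial	emotion	denial	preferred	denial
anger	emotion	anger	preferred	anger
anger	emotion	anger	synonym	bunno
fear_anxiety	emotion	fear and anxiety	preferred	fear and anxiety
fear_anxiety	emotion	fear and anxiety	synonym	fear
fear_anxiety	emotion	fear and anxiety	synonym	anxiety
fear_anxiety	emotion	fear and anxiety	synonym	bul-an
sadness_depression	emotion	sadness and depression	preferred	sadness and depression
sadness_depression	emotion	sadness and depression	synonym	sadness
sadness_depression	emotion	sadness and depression	synonym	depression
sadness_depression	emotion	sadness and depression	synonym	uul
guilt	emotion	guilt	preferred	guilt
guilt	emotion	guilt	synonym	joechaekgam
loneliness	emotion	loneliness	preferred	loneliness
loneliness	emotion	loneliness	synonym	oeroum
hope	emotion	hope	preferred	hope
hope	emotion	hope	synonym	huimang
gratitude	emotion	gratitude	preferred	gratitude
gratitude	emotion	gratitude	synonym	gamsa
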