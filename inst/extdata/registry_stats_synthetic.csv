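cancer_type_label,concept_id,incidence_rank
stomach cancer,stomach_cancer,1
colon cancer,colon_cancer,2
thyroid cancer,thyroid_cancer,3
lung cancer,lung_cancer,4
breast cancer,breast_cancer,5
liver cancer,liver_cancer,6
prostate cancer,prostate_cancer,7
pancreatic cancer,pancreatic_cancer,8
gallbladder cancer,gallbladder_cancer,9
kidney cancer,kidney_cancer,10
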