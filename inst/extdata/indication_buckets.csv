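indication,bucket
melanoma,Skin cancer
malignant melanoma,Skin cancer
metastatic melanoma,Skin cancer
squamous cell carcinoma of skin,Skin cancer
non-small cell lung cancer,Tumors of respiratory system
nsclc,Tumors of respiratory system
small cell lung cancer,Tumors of respiratory system
lung adenocarcinoma,Tumors of respiratory system
lung neoplasm malignant,Tumors of respiratory system
head and neck cancer,Head and neck cancer
squamous cell carcinoma of head and neck,Head and neck cancer
oropharyngeal cancer,Head and neck cancer
laryngeal cancer,Head and neck cancer
hodgkin's disease,Haematopoietic and lymphoid tissues
hodgkin lymphoma,Haematopoietic and lymphoid tissues
lymphoma,Haematopoietic and lymphoid tissues
multiple myeloma,Haematopoietic and lymphoid tissues
leukaemia,Haematopoietic and lymphoid tissues
renal cell carcinoma,Tumors of urinary system
bladder cancer,Tumors of urinary system
transitional cell carcinoma,Tumors of urinary system
urothelial carcinoma,Tumors of urinary system
breast cancer,Breast cancer
triple negative breast cancer,Breast cancer
gastric cancer,Gastrointestinal cancer
colorectal cancer,Gastrointestinal cancer
oesophageal carcinoma,Gastrointestinal cancer
hepatocellular carcinoma,Gastrointestinal cancer
mesothelioma,Mesothelioma
malignant mesothelioma,Mesothelioma
merkel cell carcinoma,Neuroendocrine neoplasm
neuroendocrine carcinoma,Neuroendocrine neoplasm
ovarian cancer,Tumors of female reproductive organs
cervix carcinoma,Tumors of female reproductive organs
endometrial cancer,Tumors of female reproductive organs
osteosarcoma,Bone tumor
bone neoplasm,Bone tumor
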