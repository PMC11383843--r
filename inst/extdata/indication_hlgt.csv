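term,hlgt
Glioblastoma,Nervous system neoplasms malignant and unspecified NEC
Glioblastoma multiforme,Nervous system neoplasms malignant and unspecified NEC
Glioma,Nervous system neoplasms malignant and unspecified NEC
Astrocytoma,Nervous system neoplasms malignant and unspecified NEC
Neuroblastoma,Nervous system neoplasms malignant and unspecified NEC
Brain neoplasm,Nervous system neoplasms malignant and unspecified NEC
Medulloblastoma,Nervous system neoplasms malignant and unspecified NEC
Melanoma,Skin neoplasms malignant and unspecified
Malignant melanoma,Skin neoplasms malignant and unspecified
Lung adenocarcinoma,Respiratory and mediastinal neoplasms malignant and unspecified
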