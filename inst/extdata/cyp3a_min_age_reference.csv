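name,min_age_class
alprazolam,1 day
atorvastatin,1 day
quinidine,1 day
sildenafil,1 day
solifenacin,1 day
sufentanil,1 day
tacrolimus,1 day
sirolimus,1 month
cisapride,6 months
domperidone,6 months
vincristine,6 months
tamsulosin,2 years
simvastatin,not_accurate_le_5y
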