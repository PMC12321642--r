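name,spectrum_class,route
ampicillin,narrow,iv
amoxicillin,narrow,po
cefazolin,narrow,iv
penicillin,narrow,iv
metronidazole,narrow,iv
ceftriaxone,cap_core_betalactam,iv
ampicillin-sulbactam,cap_core_betalactam,iv
azithromycin,atypical_coverage,iv
doxycycline,atypical_coverage,po
levofloxacin,targeted_broad,iv
moxifloxacin,targeted_broad,iv
aztreonam,targeted_broad,iv
ceftazidime,antipseudomonal_betalactam,iv
cefepime,antipseudomonal_betalactam,iv
piperacillin-tazobactam,antipseudomonal_betalactam,iv
meropenem,carbapenem_or_mdr,iv
imipenem-cilastatin,carbapenem_or_mdr,iv
ertapenem,carbapenem_or_mdr,iv
ceftazidime-avibactam,carbapenem_or_mdr,iv
vancomycin,anti_mrsa,iv
linezolid,anti_mrsa,iv
daptomycin,anti_mrsa,iv
ceftaroline,anti_mrsa,iv
tobramycin,adjunct_gram_negative,iv
amikacin,adjunct_gram_negative,iv
gentamicin,adjunct_gram_negative,iv
ciprofloxacin,adjunct_gram_negative,iv
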