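{
  "name": "multiplex-pneumonia-panel",
  "organisms": [
    "acinetobacter calcoaceticus-baumannii complex",
    "enterobacter cloacae complex",
    "escherichia coli",
    "haemophilus influenzae",
    "klebsiella aerogenes",
    "klebsiella oxytoca",
    "klebsiella pneumoniae group",
    "moraxella catarrhalis",
    "proteus spp",
    "pseudomonas aeruginosa",
    "serratia marcescens",
    "staphylococcus aureus",
    "streptococcus agalactiae",
    "streptococcus pneumoniae",
    "streptococcus pyogenes",
    "chlamydia pneumoniae",
    "legionella pneumophila",
    "mycoplasma pneumoniae"
  ],
  "genes": ["mecA/C", "MREJ", "OXA-48-like", "CTX-M", "KPC", "NDM", "IMP", "VIM"]
}
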