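clade,analysis,age_ma,min_ma,max_ma
Lorisiformes,AUTOsoft,31.4,37.1,NA
Lorisiformes,IRsoft,32.8,37.1,NA
Haplorhini,AUTOsoft,63.3,NA,58.9
Haplorhini,IRsoft,64.2,NA,58.9
Macaca-to-other-Papionini,IRsoft,4.5,5.5,NA
Theropithecus-to-Papio-group,IRsoft,2.4,3.5,NA
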