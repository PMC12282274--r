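id	true_group	true_subgroup
g01A_m01	G01	G01A
g01A_m02	G01	G01A
g01B_m01	G01	G01B
g01B_m02	G01	G01B
g02_m01	G02	NA
g02_m02	G02	NA
g02_m03	G02	NA
g02_m04	G02	NA
g03_m01	G03	NA
g03_m02	G03	NA
g03_m03	G03	NA
g03_m04	G03	NA
singleton_01	NA	NA
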