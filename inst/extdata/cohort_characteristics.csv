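category,level,dss,dsd
t_stage,T1a,26,1
t_stage,T1b,43,3
t_stage,T1c,117,6
t_stage,T2,80,17
t_stage,T3,7,4
t_stage,T4,6,4
histology,invasive_ductal_nos,212,27
histology,invasive_lobular,23,4
histology,mixed_lobular_ductal,38,4
histology,invasive_medullary,3,0
histology,invasive_mucinous,3,0
grade,G1,12,0
grade,G2,108,13
grade,G3,159,22
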