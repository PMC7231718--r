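covariate,level,reference
age_group,>60,1
age_group,<40,0
age_group,40-60,0
surgery,MRM,1
surgery,BCS,0
tumor_size,T3+,1
tumor_size,T1,0
tumor_size,T2,0
nodes,N2+,1
nodes,N0,0
nodes,N1,0
stage,III+,1
stage,I,0
stage,II,0
grade,poorly,1
grade,well,0
grade,moderately,0
lvi,neg,1
lvi,pos,0
er,neg,1
er,pos,0
pr,neg,1
pr,pos,0
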