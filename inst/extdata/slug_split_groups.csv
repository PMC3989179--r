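parent,group,members,group_nj,group_bi,name_applied
1,1A,1A,99,100,Arion ater
1,1B+1C,1B+1C,93,63,Arion cf. vulgaris
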