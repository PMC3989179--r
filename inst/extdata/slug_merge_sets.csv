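set_id,psh_ids,union_nj,union_bi
subfuscus_pair,7+8,0,0
iratii_pair,9+10,100,100
laeve_complex,33+34+35+36,100,100
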