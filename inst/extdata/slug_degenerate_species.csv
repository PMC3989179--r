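ssh_id,name_applied,n_haplotypes,n_individuals,mean_intra
46,Boettgerilla pallens,2,4,0.00
47,Selenochlamys ysbryda,2,6,0.00
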