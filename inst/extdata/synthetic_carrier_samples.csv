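# synthetic example sample sheet
well,sample_id,material,replicate,marker_snp
LCL001_g1,LCL001,gDNA,1,sim_snp
LCL001_g2,LCL001,gDNA,2,sim_snp
LCL001_g3,LCL001,gDNA,3,sim_snp
LCL001_g4,LCL001,gDNA,4,sim_snp
LCL001_c1,LCL001,cDNA,1,sim_snp
LCL001_c2,LCL001,cDNA,2,sim_snp
LCL001_c3,LCL001,cDNA,3,sim_snp
LCL001_c4,LCL001,cDNA,4,sim_snp
LCL001_p1,LCL001,cDNA_puromycin,1,sim_snp
LCL001_p2,LCL001,cDNA_puromycin,2,sim_snp
LCL001_p3,LCL001,cDNA_puromycin,3,sim_snp
LCL001_p4,LCL001,cDNA_puromycin,4,sim_snp
NTC1,NTC,NTC,1,sim_snp
NTC2,NTC,NTC,2,sim_snp
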