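bedroom_type,n,mean_partners,mean_frequency,mean_degree_centrality
three_bed,7,1.10,2.86,0.07
four_bed_common,15,2.43,4.60,0.04
four_bed_corridor,18,1.85,4.44,0.23
five_bed,8,2.79,2.75,0.06
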