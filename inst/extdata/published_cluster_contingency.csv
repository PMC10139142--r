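cluster,three_bed,four_bed_corridor,four_bed_common,five_bed
diverse_common,0,5,0,0
diverse_bedroom,0,2,7,1
nonroommate_focused,1,6,3,1
roommate_focused,2,3,5,4
restricted,4,2,0,2
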