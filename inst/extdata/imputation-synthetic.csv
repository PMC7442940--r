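sex,age_min,age_max,sbp,total_cholesterol,hdl_cholesterol
female,35,39,114,5.0,1.55
female,40,44,116,5.2,1.55
female,45,49,119,5.4,1.57
female,50,54,122,5.6,1.58
female,55,59,126,5.8,1.58
female,60,64,130,5.9,1.57
female,65,69,134,5.8,1.56
female,70,75,138,5.7,1.55
male,35,39,122,5.4,1.25
male,40,44,124,5.5,1.24
male,45,49,126,5.6,1.23
male,50,54,128,5.6,1.22
male,55,59,131,5.5,1.22
male,60,64,134,5.4,1.23
male,65,69,137,5.2,1.24
male,70,75,140,5.1,1.25
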