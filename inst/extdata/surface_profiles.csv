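surface_class,wfps_lo,wfps_hi,no3_lo,no3_hi,nh4_lo,nh4_hi,cn_ratio,flux_median,flux_lo,flux_hi,assumed_fields
vegetated_holocene,0.06,0.15,0,0.5,0,5,38,-4,-25,10,no3;nh4;flux_lo;flux_hi
bare_fresh_yedoma,0.67,1.00,0,0.5,20,50,14.5,-9,-147,50,no3;nh4_hi;flux_hi
bare_earlier_yedoma,0.40,0.80,0,1,5,30,14.5,10,-25,100,wfps;no3;nh4;flux
yedoma_moss,0.42,0.84,0,10,2,20,14.5,100,10,500,no3;nh4;flux
yedoma_grass,0.42,0.84,1,30,1,15,14.5,548,133,6286,no3;nh4
bare_sand,0.30,0.70,0,0.2,0,2,14.5,0,-5,5,wfps;no3;nh4;flux
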