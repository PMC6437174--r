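node_id,kind,pressure_mmHg,flow_ul_s,hd
37,pressure,10,NA,NA
38,pressure,16.25742253834853,NA,NA
39,pressure,30,NA,NA
40,pressure,20.442152317876484,NA,NA
41,pressure,28.812865709197887,NA,NA
42,pressure,21.533367402527052,NA,NA
43,pressure,24.45152973564462,NA,NA
44,pressure,27.82652154049964,NA,NA
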