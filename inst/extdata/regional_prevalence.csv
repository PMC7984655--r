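region,prev_lo_per_100k,prev_hi_per_100k,mz_probandwise
Canada,68,248,0.253
Northern US,100,160,0.314
Southern US,22,112,0.174
Finland,52,93,0.462
Denmark,110,110,0.240
British Isles,74,193,0.400
France,32,65,0.111
Sardinia,144,152,0.222
Italy,38,90,0.145
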