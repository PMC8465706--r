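organ,mass_g,blood_fraction_pct
heart_wall,0.291,1.0
kidneys,0.374,4.8
liver,2.150,23.0
lungs,0.107,2.6
bone_marrow,1.049,4.0
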