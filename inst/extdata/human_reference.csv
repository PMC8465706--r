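organ,mass_g,blood_fraction_pct
heart_wall,291,1.0
kidneys,357,2.0
liver,1810,10.0
lungs,950,10.5
bone_marrow,1064,4.0
spleen,187,1.4
tumor,38,0.0
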