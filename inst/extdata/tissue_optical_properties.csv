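tissue,wavelength_nm,mua_mm,musp_mm,refractive_index
extracerebral,780,0.0164,0.74,1.4
extracerebral,850,0.0191,0.64,1.4
csf,780,0.0026,0.32,1.4
csf,850,0.0041,0.32,1.4
grey,780,0.0178,0.746,1.4
grey,850,0.0186,0.642,1.4
white,780,0.0167,0.906,1.4
white,850,0.0208,0.841,1.4
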