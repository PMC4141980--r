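wavelength_nm,eps_hbo,eps_hbr,convention,units,citation
780,1.6947026e-04,2.5379093e-04,natural_log,mm^-1.uM^-1,"Compiled haemoglobin spectra (Gratzer/Kollias tabulation as distributed by Prahl), converted from log10 molar cm^-1 to natural-log mm^-1 uM^-1"
850,2.4361350e-04,1.5918235e-04,natural_log,mm^-1.uM^-1,"Compiled haemoglobin spectra (Gratzer/Kollias tabulation as distributed by Prahl), converted from log10 molar cm^-1 to natural-log mm^-1 uM^-1"
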