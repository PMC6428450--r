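# Molar extinction coefficients of hemoglobin, Prahl compilation (decadic,
# cm^-1 per mol/L), converted here to natural-log units of mm^-1 per uM:
# eps_ln[mm^-1 uM^-1] = eps_decadic[cm^-1 M^-1] * ln(10) * 1e-7
# version: prahl-1998, converted 2026
wavelength_nm,eps_hbo,eps_hbr
760,1.349314864e-04,3.565599068e-04
850,2.436135028e-04,1.591823126e-04
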