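# Specific decadic extinction coefficients of hemoglobin, 1/cm per (mol/l),
# approximate tabulated compendium values at the two source wavelengths.
# Editable; no analysis result depends on the specific numbers, only on
# forward/inverse consistency of the 2x2 system.
wavelength_nm,o2hb,hhb
760,1486.6,3843.7
870,2696.0,1674.0
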