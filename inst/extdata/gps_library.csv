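# Gauss-peak-spectra template library for diatom pigments in 100% acetone.
# SYNTHETIC parameterisation: peak centers/widths follow literature-typical
# acetone absorption maxima and vibronic structure for each pigment; it is an
# internally consistent stand-in for a published GPS library, not a
# transcription of one. Each pigment's unit-concentration spectrum is
# sum_k amplitude_k * exp(-(lambda - center_nm_k)^2 / (2 * sd_nm_k^2)).
pigment,center_nm,sd_nm,amplitude
chl_a,410,12,0.50
chl_a,430,12,1.00
chl_a,615,12,0.14
chl_a,662,9,0.85
chl_c,444,11,1.00
chl_c,580,10,0.18
chl_c,630,9,0.30
pheophytin_a,409,11,1.00
pheophytin_a,505,12,0.12
pheophytin_a,535,10,0.12
pheophytin_a,666,9,0.55
beta_carotene,426,13,0.55
beta_carotene,452,12,1.00
beta_carotene,478,11,1.00
fucoxanthin,395,18,0.35
fucoxanthin,447,24,1.00
diadinoxanthin,423,7.5,0.70
diadinoxanthin,446,7.5,1.00
diadinoxanthin,474,7,0.95
diatoxanthin,434,12,0.85
diatoxanthin,457,12,1.00
diatoxanthin,486,11,0.55
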