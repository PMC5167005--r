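# Decadic molar extinction coefficients of human hemoglobin, cm^-1 / (mol/L).
# Transcribed from the compilation by S. Prahl (Oregon Medical Laser Center,
# "Optical absorption of hemoglobin"), based on the data of W. B. Gratzer and
# N. Kollias. Values at the two acquisition wavelengths of the NIRSport
# continuous-wave system.
wavelength_nm	eps_o2hb	eps_hhb
760	586.0	1548.52
850	1058.0	691.32
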