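# Material properties used by the stopping-power / scattering model.
# Columns (tab separated):
#   name              label used throughout the package
#   density           bulk density [g/cm^3]; the absorber plastic density is
#                     re-fitted at calibration time (see calibrate_absorber)
#   i_ev              mean excitation energy I [eV]
#   z_over_a          <Z/A> [mol/g]
#   x0_g_cm2          radiation length X0 [g/cm^2]
#   lambda_g_cm2      nuclear interaction removal length [g/cm^2]
#   wer               energy-independent mass-stopping ratio relative to water
#   composition       informal composition note
name	density	i_ev	z_over_a	x0_g_cm2	lambda_g_cm2	wer	composition
water	1.0	75.0	0.55509	36.08	85.0	1.0	H2O
abs_plastic	1.05	68.5	0.53949	43.6	85.0	0.962	C15H17N
brass	8.52	324.0	0.45636	12.74	85.0	0.672	Cu70Zn30
air	0.0012048	85.7	0.49919	36.62	85.0	0.984	N2/O2/Ar at NTP
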