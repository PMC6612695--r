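# Reference unrestricted electronic stopping powers of liquid water for
# protons, MeV cm^2/g (ICRU 49 / NIST PSTAR tabulation), transcribed as an
# independent check of the package's Bethe implementation.
energy_mev,mass_stopping_mev_cm2_g
10,45.67
50,12.45
100,7.289
200,4.492
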