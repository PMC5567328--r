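key	value
gbif_total_occ_millions	649.79
gbif_total_sp_thousands	1200.38
species_with_1_occ	212911
species_with_2_19_occ	446643
species_with_ge20_occ	353843
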