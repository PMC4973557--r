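property,unit,standard_batch,optimized_fed_batch
max_biomass_density,g_dw/L,1.38,3.40
max_carotene_density,mg/L,67.73,140.06
max_carotene_fraction,mg/g_dw,49.09,59.53
max_carotene_productivity,mg/L/d,11.53,17.48
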