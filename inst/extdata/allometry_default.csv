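allometry_key,form,coeff_a,exponent_c,dbh_min_cm,dbh_max_cm,source
broadleaf_default,power_law,0.12,2.40,5,80,Generic temperate broadleaf power law; synthetic package default (not taken from any single published study)
conifer_default,power_law,0.10,2.35,5,80,Generic temperate conifer power law; synthetic package default (not taken from any single published study)
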