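class_id,label,family,A,k,p,b,residual_error_cm,canopy_fraction_pct,allometry_key
1,Acer campestre; Acer platanoides; Acer sp.,saturating,202.9173,0.0019,0.7992,NA,5.48,12.9,broadleaf_default
2,Aesculus hippocastanum,saturating,175.5828,0.0042,0.8958,NA,6.57,13.4,broadleaf_default
3,Fagus sylvatica,saturating,202.9173,0.0019,0.7992,NA,6.15,10.4,broadleaf_default
4,Pinus sylvestris,gompertz,135.4549,0.0152,NA,3.1143,4.74,11.3,conifer_default
5,Platanus hispanica,saturating,170.5888,0.0047,0.913,NA,4.95,1.9,broadleaf_default
6,Populus nigra; Populus alba,saturating,93.5402,0.0152,1.1518,NA,10.77,1.8,broadleaf_default
7,Quercus robur; Quercus rubra; Quercus sp.,gompertz,70.2797,0.0289,NA,2.8528,4.03,8.6,broadleaf_default
8,Tilia cordata; Tilia x vulgaris; Tilia platyphyllos,saturating,56.4678,0.0182,1.053,NA,5.71,13.2,broadleaf_default
9,Betula pendula,saturating,199.1001,0.0029,0.8865,NA,4.48,NA,broadleaf_default
10,Robinia pseudoacacia,gompertz,116.6451,0.0198,NA,3.1542,5.40,NA,broadleaf_default
mix,Mix of dominant species above,mix,NA,NA,NA,NA,NA,26.5,mix
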