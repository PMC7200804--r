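tissue,f_neutral_lipid,f_phospholipid,f_water,adipose
plasma,0.0023,0.0013,0.945,0
adipose,0.853,0.0016,0.144,1
liver,0.0348,0.0252,0.751,0
kidney,0.0121,0.0240,0.788,0
gut,0.0292,0.0138,0.771,0
others,0.0238,0.0072,0.756,0
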