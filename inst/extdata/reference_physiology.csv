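tissue,volume_frac_bw,flow_frac_co
gut,0.0170,0.155
liver,0.0260,0.065
kidney,0.0044,0.190
fat,0.1900,0.050
blood,0.0770,NA
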