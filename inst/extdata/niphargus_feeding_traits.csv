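species,single_nail_dactylus,carpal_setae_gnathopod2,ischium_setae_gnathopod1
NKA,0,1,0
NKB,0,0,0
NSA,1,1,1
NSB,1,1,1
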