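fleet,group,catch,price
fleet01,shrimp,0.19447591438229733,1
fleet01,benthic_inverts,7.2973261350618905,1
fleet01,small_demersals,0.044791313032172535,1
fleet02,grouper,0.0037860307728476337,1
fleet02,small_demersals,0.040265763744711185,1
fleet02,forage_fish,0.5783532853338381,1
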